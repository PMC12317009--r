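#' Ten-element shape feature vector of a laminar profile
#'
#' Summarizes a GLI profile y(x) over normalized depth x by central-moment
#' descriptors: mean density (arithmetic mean of y), depth centroid
#' (mean x, weighted by y), standard deviation, skewness and kurtosis of x
#' under weights y, plus the same five features of the profile's first
#' derivative. Derivative weights are the absolute first differences so the
#' weighted moments remain defined. Skewness is standardized by std^3,
#' kurtosis by std^4. A profile whose weighted std is zero reports skewness
#' and kurtosis 0 with a warning; an all-zero profile is an error.
#'
#' @param profile Numeric vector (length >= 5) of GLI values.
#' @param depth Normalized-depth grid; defaults to equidistant points on
#'   \[0, 1\].
#' @return Named numeric vector of length 10.
#' @examples
#' profile_features(c(0.2, 0.4, 0.6, 0.8), depth = c(0, 1/3, 2/3, 1))
#' @export
profile_features <- function(profile, depth = NULL) {
  n <- length(profile)
  if (n < 4) stop_validation("profile must have length >= 4")
  if (is.null(depth)) depth <- seq(0, 1, length.out = n)
  if (length(depth) != n) stop_validation("depth grid length mismatch")
  if (all(profile == 0)) {
    stop_validation("all-zero profile: moment weights undefined")
  }
  moments <- function(x, w, mean_density, what) {
    sw <- sum(w)
    if (sw <= 0) {
      warning(sprintf("%s weights all zero; centroid set to depth midrange, higher moments to 0", what))
      return(c(mean_density, mean(range(x)), 0, 0, 0))
    }
    mu <- sum(x * w) / sw
    v <- sum((x - mu)^2 * w) / sw
    s <- sqrt(v)
    if (s == 0) {
      warning(sprintf("%s has zero weighted std; skewness/kurtosis set to 0", what))
      sk <- ku <- 0
    } else {
      sk <- sum((x - mu)^3 * w) / sw / s^3
      ku <- sum((x - mu)^4 * w) / sw / s^4
    }
    c(mean_density, mu, s, sk, ku)
  }
  f1 <- moments(depth, profile, mean(profile), "profile")
  d <- abs(diff(profile))
  xd <- (depth[-1] + depth[-n]) / 2
  f2 <- moments(xd, d, mean(d), "profile derivative")
  setNames(c(f1, f2),
           c("mean_gli", "mean_x", "sd_x", "skew_x", "kurt_x",
             "d_mean", "d_mean_x", "d_sd_x", "d_skew_x", "d_kurt_x"))
}

#' Feature matrix of a profile set
#'
#' Applies [profile_features()] to every profile. For `profile_set` /
#' `synthetic_ribbon` objects the depth grid is the bin-midpoint grid the
#' profiles were sampled on.
#'
#' @param x `profile_set`, `synthetic_ribbon`, or numeric matrix (one
#'   profile per row).
#' @param depth Optional depth grid passed to [profile_features()].
#' @return `n x 10` numeric matrix.
#' @export
feature_matrix <- function(x, depth = NULL) {
  p <- as_profile_matrix(x)
  if (is.null(depth) &&
      (inherits(x, "profile_set") || inherits(x, "synthetic_ribbon"))) {
    depth <- (seq_len(ncol(p)) - 0.5) / ncol(p)
  }
  t(apply(p, 1L, profile_features, depth = depth))
}

# Two-sample Hotelling T^2 p-value from a squared Mahalanobis distance
# between group means (pooled covariance), via the exact F transform.
hotelling_p <- function(md2, n1, n2, p = 10) {
  t2 <- (n1 * n2 / (n1 + n2)) * md2
  df2 <- n1 + n2 - p - 1
  if (df2 <= 0) stop_validation("blocks too small for a %d-dim Hotelling test", p)
  f <- df2 / ((n1 + n2 - 2) * p) * t2
  pf(f, p, df2, lower.tail = FALSE)
}

# Pooled within-block covariance with optional shrinkage toward a scaled
# identity: S_reg = (1 - lambda) S + lambda tr(S)/p I.
pooled_cov <- function(f1, f2, shrinkage = 0) {
  s <- ((nrow(f1) - 1) * cov(f1) + (nrow(f2) - 1) * cov(f2)) /
    (nrow(f1) + nrow(f2) - 2)
  if (shrinkage > 0) {
    p <- ncol(s)
    scale_ <- sum(diag(s)) / p
    if (scale_ <= 0) scale_ <- 1  # fully degenerate blocks: identity target
    s <- (1 - shrinkage) * s + shrinkage * scale_ * diag(p)
  }
  s
}

#' Sliding-window Mahalanobis distance function along a ribbon
#'
#' At every admissible border position k (a border after traverse k), the
#' Mahalanobis distance between the mean feature vectors of the two adjacent
#' blocks of `block_size` profiles, \[k-b+1, k\] and \[k+1, k+b\], is
#' computed with the pooled within-block covariance of the per-profile
#' feature vectors. Block averaging increases the signal-to-noise ratio;
#' maxima of the distance function mark the most dissimilar laminar
#' patterns, i.e. candidate borders. Significance is assessed per position
#' by a two-sample Hotelling T-squared test with Bonferroni correction over
#' the number of positions.
#'
#' @param x Profiles (`profile_set`, `synthetic_ribbon` or matrix) or a
#'   precomputed `n x 10` feature matrix (`features = TRUE`).
#' @param block_size Profiles per block (b >= 11 unless `shrinkage > 0`).
#' @param shrinkage Covariance shrinkage weight in \[0, 1\] toward a scaled
#'   identity (0 = pure pooled sample covariance).
#' @param features Set TRUE if `x` is already a feature matrix.
#' @return Object of class `md_function`: `positions` (border-after-traverse
#'   indices), `md` (Mahalanobis distance, >= 0), `p_raw`, `p_corrected`
#'   (Bonferroni, capped at 1), `block_size`, `n_positions`.
#' @export
md_function <- function(x, block_size, shrinkage = 0, features = FALSE) {
  fm <- if (features) x else feature_matrix(x)
  n <- nrow(fm); p <- ncol(fm)
  b <- as.integer(block_size)
  if (2L * b > n) stop_validation("2*block_size exceeds the number of profiles")
  if (b <= p && shrinkage <= 0) {
    stop_validation("block_size must exceed the feature dimension (%d) unless shrinkage > 0", p)
  }
  positions <- seq.int(b, n - b)
  np <- length(positions)
  md2 <- numeric(np)
  praw <- numeric(np)
  for (i in seq_len(np)) {
    k <- positions[i]
    f1 <- fm[(k - b + 1L):k, , drop = FALSE]
    f2 <- fm[(k + 1L):(k + b), , drop = FALSE]
    s <- pooled_cov(f1, f2, shrinkage)
    d <- colMeans(f1) - colMeans(f2)
    if (max(abs(d)) < 1e-12) {
      # identical block means (e.g. a noise-free homogeneous ribbon): the
      # distance is 0 whatever the covariance
      md2[i] <- 0
      praw[i] <- 1
      next
    }
    sol <- tryCatch(solve(s, d), error = function(e) NULL)
    if (is.null(sol)) {
      stop_validation("singular pooled covariance at position %d; enable shrinkage", k)
    }
    md2[i] <- max(0, sum(d * sol))
    praw[i] <- hotelling_p(md2[i], b, b, p)
  }
  structure(
    list(positions = positions, md = sqrt(md2), p_raw = praw,
         p_corrected = pmin(praw * np, 1), block_size = b, n_positions = np),
    class = "md_function")
}

#' @export
print.md_function <- function(x, ...) {
  i <- which.max(x$md)
  cat(sprintf("<md_function: b = %d, %d positions, peak MD %.2f at %d (p_corr = %.3g)>\n",
              x$block_size, x$n_positions, x$md[i], x$positions[i],
              x$p_corrected[i]))
  invisible(x)
}

# Local maxima of a vector with plateaus collapsed to their midpoint
# (rounded down, so the lower index wins on even plateaus).
local_maxima <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- i == 1L || r$values[i - 1L] < r$values[i]
    right_ok <- i == k || r$values[i + 1L] < r$values[i]
    if (left_ok && right_ok) {
      out <- c(out, (starts[i] + ends[i]) %/% 2L)
    }
  }
  out
}

#' Detect cytoarchitectonic borders from a profile set
#'
#' Runs [md_function()] over a range of block sizes (default 12-24 profiles
#' per block). For each block size, local maxima of the Mahalanobis distance
#' whose Bonferroni-corrected Hotelling p-value is below `alpha` are
#' candidate borders; candidates from different block sizes within
#' `merge_window` traverses of each other are merged (reported position:
#' median of the supporting candidates), and merged candidates supported by
#' at least `min_support` block sizes are accepted. Requiring support across
#' block sizes replaces a second multiplicity correction across block sizes.
#'
#' @param x Profiles or feature matrix (see [md_function()]).
#' @param block_range Integer vector `c(min, max)` of block sizes.
#' @param alpha Significance level on Bonferroni-corrected p-values.
#' @param min_support Minimum number of supporting block sizes; default half
#'   of the admissible block sizes, rounded up.
#' @param merge_window Maximum traverse distance for merging candidates
#'   across block sizes.
#' @param shrinkage Covariance shrinkage passed to [md_function()].
#' @param features Set TRUE if `x` is already a feature matrix.
#' @return Object of class `border_set`: `borders` (sorted traverse
#'   indices; a border at b separates traverses 1..b and b+1..), `support`
#'   (list of supporting block sizes per border), `alpha`, `block_sizes`,
#'   `candidates` (all per-block-size significant maxima).
#' @examples
#' a <- laminar_model(c(0.1, 0.3, 0.3, 0.1, 0.2),
#'                    c(0.60, 0.40, 0.30, 0.50, 0.45), 0.03, "A")
#' b <- laminar_model(c(0.1, 0.3, 0.3, 0.1, 0.2),
#'                    c(0.60, 0.55, 0.30, 0.35, 0.45), 0.03, "B")
#' rib <- render_ribbon(list(a, b), c(76, 86), seed = 1)
#' detect_borders(rib)$borders
#' @export
detect_borders <- function(x, block_range = c(12, 24), alpha = 0.001,
                           min_support = NULL, merge_window = 5,
                           shrinkage = 0, features = FALSE) {
  if (!(alpha > 0 && alpha < 1)) stop_validation("alpha must be in (0, 1)")
  fm <- if (features) x else feature_matrix(x)
  n <- nrow(fm); p <- ncol(fm)
  bmin_admissible <- if (shrinkage > 0) 2L else p + 1L
  sizes <- seq.int(block_range[1], block_range[2])
  sizes <- sizes[sizes >= bmin_admissible & 2L * sizes <= n]
  if (!length(sizes)) {
    stop_validation("no admissible block sizes in [%d, %d] for %d profiles",
                    block_range[1], block_range[2], n)
  }
  if (is.null(min_support)) min_support <- ceiling(length(sizes) / 2)
  cand_pos <- integer(0); cand_b <- integer(0)
  for (b in sizes) {
    mf <- md_function(fm, b, shrinkage = shrinkage, features = TRUE)
    lm <- local_maxima(mf$md)
    sig <- lm[mf$p_corrected[lm] < alpha]
    if (length(sig)) {
      cand_pos <- c(cand_pos, mf$positions[sig])
      cand_b <- c(cand_b, rep(b, length(sig)))
    }
  }
  borders <- integer(0); support <- list()
  if (length(cand_pos)) {
    ord <- order(cand_pos, cand_b)
    cp <- cand_pos[ord]; cb <- cand_b[ord]
    cluster <- cumsum(c(1L, diff(cp) > merge_window))
    for (cl in unique(cluster)) {
      sel <- cluster == cl
      sup <- sort(unique(cb[sel]))
      if (length(sup) >= min_support) {
        pos <- as.integer(floor(median(cp[sel])))
        borders <- c(borders, pos)
        support <- c(support, list(sup))
      }
    }
  }
  ord <- order(borders)
  structure(
    list(borders = borders[ord], support = support[ord], alpha = alpha,
         block_sizes = sizes, min_support = as.integer(min_support),
         merge_window = merge_window,
         candidates = data.frame(position = cand_pos, block_size = cand_b)),
    class = "border_set")
}

#' @export
print.border_set <- function(x, ...) {
  if (!length(x$borders)) {
    cat("<border_set: no significant borders>\n")
  } else {
    cat(sprintf("<border_set: %d border(s) at [%s], alpha = %g>\n",
                length(x$borders), paste(x$borders, collapse = ", "),
                x$alpha))
  }
  invisible(x)
}

#' Plot a Mahalanobis distance function
#'
#' Draws MD against profile position with significant positions highlighted,
#' mirroring the standard presentation of sliding-window border-detection
#' output.
#'
#' @param x An `md_function`.
#' @param alpha Highlight positions with corrected p below this level.
#' @param ... Passed to [plot()].
#' @export
plot.md_function <- function(x, alpha = 0.001, ...) {
  plot(x$positions, x$md, type = "l", xlab = "profile position",
       ylab = "Mahalanobis distance",
       main = sprintf("block size %d", x$block_size), ...)
  sig <- x$p_corrected < alpha
  if (any(sig)) points(x$positions[sig], x$md[sig], pch = 16, col = 2)
  invisible(x)
}
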