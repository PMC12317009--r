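#' Mean feature vector of an area from sampled profiles
#'
#' Characterizes one area (per hemisphere) by the elementwise mean of the
#' 10-element feature vectors of profiles sampled from several sections:
#' by default 45 profiles from each of 3 sections, sampled without
#' replacement, seed-deterministic.
#'
#' @param sections List of profile sources (`profile_set`,
#'   `synthetic_ribbon` or matrix), one per section; each must supply at
#'   least `n_per_section` profiles.
#' @param n_per_section Profiles sampled per section.
#' @param seed Optional RNG seed.
#' @return Named numeric feature vector of length 10.
#' @export
mean_area_feature <- function(sections, n_per_section = 45, seed = NULL) {
  if (!is.list(sections)) sections <- list(sections)
  mats <- lapply(sections, as_profile_matrix)
  short <- vapply(mats, nrow, 0L) < n_per_section
  if (any(short)) {
    stop_validation("section %d supplies %d < %d profiles",
                    which(short)[1], nrow(mats[[which(short)[1]]]),
                    n_per_section)
  }
  feats <- with_seed(seed, {
    lapply(mats, function(m) {
      idx <- sample.int(nrow(m), n_per_section)
      feature_matrix(m[idx, , drop = FALSE],
                     depth = (seq_len(ncol(m)) - 0.5) / ncol(m))
    })
  })
  colMeans(do.call(rbind, feats))
}

#' Euclidean distance matrix between area feature vectors
#'
#' @param table Numeric matrix of feature vectors, one labelled row per
#'   area (rownames required), or a data.frame of numeric columns.
#' @param standardize Z-score each feature across areas before computing
#'   distances (off by default; the 10 features live on different scales,
#'   so standardizing changes which features dominate).
#' @return Square symmetric matrix with zero diagonal, labelled like the
#'   input rows.
#' @export
distance_matrix <- function(table, standardize = FALSE) {
  m <- as.matrix(table)
  if (nrow(m) < 2L) stop_validation("need at least 2 areas")
  if (!all(is.finite(m))) stop_validation("non-finite feature values")
  if (is.null(rownames(m))) rownames(m) <- paste0("area", seq_len(nrow(m)))
  if (standardize) {
    s <- apply(m, 2L, sd)
    s[s == 0] <- 1
    m <- scale(m, center = TRUE, scale = s)
  }
  as.matrix(dist(m))
}

check_distance_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop_validation("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-12) stop_validation("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop_validation("distance matrix diagonal must be 0")
  if (any(D < 0)) stop_validation("distances must be >= 0")
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  D
}

stress1 <- function(X, D) {
  dhat <- as.matrix(dist(X))
  lo <- lower.tri(D)
  sqrt(sum((dhat[lo] - D[lo])^2) / sum(D[lo]^2))
}

#' Metric multidimensional scaling by majorization
#'
#' Least-squares metric MDS minimizing stress-1,
#' `sqrt(sum((dhat - d)^2) / sum(d^2))`, by iterative majorization (the
#' Guttman transform), starting from the classical-scaling configuration
#' plus random restarts; the best restart is returned. The configuration is
#' centred at the origin (it is determined only up to rotation/reflection).
#'
#' @param D Distance matrix (square symmetric, zero diagonal).
#' @param dims Embedding dimension (< number of labels).
#' @param n_restarts Number of starts (first = classical scaling, rest
#'   random).
#' @param seed RNG seed for the random restarts.
#' @param max_iter Majorization iterations per restart.
#' @param tol Convergence: stop when the stress decrease falls below `tol`.
#' @return Object of class `mds_embedding`: `points` (labelled matrix),
#'   `stress`, `converged`, `restart` (index of the winning start).
#' @export
mds_embed <- function(D, dims = 2, n_restarts = 8, seed = 1,
                      max_iter = 500, tol = 1e-12) {
  D <- check_distance_matrix(D)
  n <- nrow(D)
  if (dims >= n) stop_validation("dims must be < number of labels")
  starts <- with_seed(seed, {
    s <- list(suppressWarnings(cmdscale(D, k = dims)))
    if (ncol(s[[1]]) < dims) {
      s[[1]] <- cbind(s[[1]], matrix(0, n, dims - ncol(s[[1]])))
    }
    c(s, lapply(seq_len(max(0L, n_restarts - 1L)), function(i) {
      matrix(rnorm(n * dims, sd = max(D) / 2 + 1e-12), n, dims)
    }))
  })
  best <- NULL
  for (r in seq_along(starts)) {
    X <- starts[[r]]
    s_old <- stress1(X, D)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dhat <- as.matrix(dist(X))
      ratio <- ifelse(dhat > 1e-12, D / dhat, 0)
      B <- -ratio
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- (B %*% X) / n
      s_new <- stress1(X, D)
      if (s_old - s_new < tol) { converged <- TRUE; break }
      s_old <- s_new
    }
    s_final <- stress1(X, D)
    if (is.null(best) || s_final < best$stress) {
      best <- list(points = X, stress = s_final, converged = converged,
                   restart = r)
    }
  }
  if (!best$converged) {
    stop_validation("MDS did not converge in any restart (best stress %.4g)",
                    best$stress)
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- rownames(D)
  structure(list(points = pts, stress = best$stress,
                 converged = best$converged, restart = best$restart),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding: %d labels in %dD, stress = %.4g>\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}

#' UPGMA hierarchical clustering with Newick export
#'
#' Unweighted pair group method with arithmetic mean: repeatedly merges the
#' closest pair of clusters, updating distances as the size-weighted mean of
#' the members' distances (equivalently, the unweighted mean over all
#' inter-cluster leaf pairs). Node heights are half the merge distance, so
#' the tree is ultrametric and its cophenetic distances reproduce an
#' ultrametric input exactly. Ties between closest pairs are broken by the
#' lexicographically smallest label pair and counted.
#'
#' @param D Distance matrix (square symmetric, zero diagonal, n >= 2).
#' @return Object of class `upgma_tree`: `merge` (hclust convention:
#'   negative = leaf), `height` (merge heights = distance / 2), `labels`,
#'   `newick` (with branch lengths), `n_ties`.
#' @examples
#' D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma_tree(D)$newick
#' @export
upgma_tree <- function(D) {
  D <- check_distance_matrix(D)
  n <- nrow(D)
  if (n < 2L) stop_validation("need at least 2 taxa")
  labels <- rownames(D)
  d <- D
  active <- seq_len(n)            # column indices still active
  node_of <- -seq_len(n)          # hclust id of each active cluster
  size <- rep(1L, n)
  first_label <- labels           # lexicographic tie-break key
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  n_ties <- 0L
  for (m in seq_len(n - 1L)) {
    na <- length(active)
    dm <- d[active, active, drop = FALSE]
    dm[upper.tri(dm, diag = TRUE)] <- Inf
    best <- min(dm)
    cand <- which(dm == best, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      n_ties <- n_ties + 1L
      keys <- apply(cand, 1L, function(rc) {
        pair <- sort(c(first_label[active[rc[1]]], first_label[active[rc[2]]]))
        paste(pair, collapse = "\r")
      })
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- active[cand[1, 2]]; j <- active[cand[1, 1]]  # col < row in lower tri
    hi <- min(i, j); lo <- max(i, j)
    merge[m, ] <- sort(c(node_of[hi], node_of[lo]))
    height[m] <- best / 2
    # proportional (arithmetic-mean) distance update into slot hi
    others <- setdiff(active, c(hi, lo))
    if (length(others)) {
      newd <- (size[hi] * d[hi, others] + size[lo] * d[lo, others]) /
        (size[hi] + size[lo])
      d[hi, others] <- newd; d[others, hi] <- newd
    }
    size[hi] <- size[hi] + size[lo]
    node_of[hi] <- m
    first_label[hi] <- min(first_label[hi], first_label[lo])
    active <- setdiff(active, lo)
  }
  tree <- structure(list(merge = merge, height = height, labels = labels,
                         n_ties = n_ties),
                    class = "upgma_tree")
  tree$newick <- as_newick(tree)
  tree
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree: %d leaves, root height %.4g>\n%s\n",
              length(x$labels), max(x$height), x$newick))
  invisible(x)
}

#' Newick serialization of a UPGMA tree
#'
#' Branch lengths encode the ultrametric: each branch is the parent merge
#' height minus the child's height (leaves sit at height 0).
#'
#' @param tree A [upgma_tree()].
#' @param digits Significant digits for branch lengths.
#' @return Newick string terminated by `;`.
#' @export
as_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "upgma_tree"))
  node_str <- function(id, parent_h) {
    if (id < 0) {
      h <- 0
      lab <- tree$labels[-id]
      sprintf("%s:%s", lab, format(parent_h - h, digits = digits))
    } else {
      h <- tree$height[id]
      kids <- vapply(tree$merge[id, ], node_str, "", parent_h = h)
      body <- sprintf("(%s,%s)", kids[1], kids[2])
      if (is.na(parent_h)) body
      else sprintf("%s:%s", body, format(parent_h - h, digits = digits))
    }
  }
  paste0(node_str(nrow(tree$merge), NA_real_), ";")
}

#' Cophenetic distance matrix of a UPGMA tree
#'
#' The cophenetic distance between two leaves is twice the height of their
#' lowest common merge (the merge distance at which they first join).
#'
#' @param tree A [upgma_tree()].
#' @return Square symmetric matrix in the order of `tree$labels`.
#' @export
cophenetic_distances <- function(tree) {
  n <- length(tree$labels)
  members <- vector("list", n - 1L)
  out <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  get_members <- function(id) if (id < 0) -id else members[[id]]
  for (m in seq_len(n - 1L)) {
    a <- get_members(tree$merge[m, 1]); b <- get_members(tree$merge[m, 2])
    out[a, b] <- out[b, a] <- 2 * tree$height[m]
    members[[m]] <- c(a, b)
  }
  out
}

#' Cut a UPGMA tree into k groups
#'
#' @param tree A [upgma_tree()].
#' @param k Number of groups.
#' @return Named integer vector of group memberships.
#' @export
cut_upgma <- function(tree, k) {
  n <- length(tree$labels)
  stopifnot(k >= 1, k <= n)
  groups <- seq_len(n)
  members <- vector("list", n - 1L)
  get_members <- function(id) if (id < 0) -id else members[[id]]
  for (m in seq_len(n - k)) {
    a <- get_members(tree$merge[m, 1]); b <- get_members(tree$merge[m, 2])
    groups[b] <- groups[a][1]
    members[[m]] <- c(a, b)
  }
  setNames(as.integer(factor(groups)), tree$labels)
}
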