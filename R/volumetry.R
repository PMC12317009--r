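#' Cavalieri volume estimate from serial sections
#'
#' Volume of an area from cross-sectional areas measured on equidistant
#' histological sections: `sum(section_areas) * thickness_mm * interval *
#' shrinkage`. The shrinkage factor (ratio of fresh to processed volume)
#' corrects for volume loss during histological processing; with 20 um
#' sections and every 15th section measured, `thickness_mm = 0.02` and
#' `interval = 15`.
#'
#' @param section_areas Cross-sectional areas (mm^2), one per measured
#'   section; all >= 0.
#' @param thickness_mm Section thickness (mm, > 0).
#' @param interval Sampling interval in sections (>= 1).
#' @param shrinkage Fresh/processed volume ratio (>= 0; 1 = no correction).
#' @return Volume in mm^3.
#' @examples
#' cavalieri_volume(c(10, 10, 10), 0.02, 15)  # 9 mm^3
#' @export
cavalieri_volume <- function(section_areas, thickness_mm = 0.02,
                             interval = 15, shrinkage = 1) {
  if (any(section_areas < 0)) stop_validation("section areas must be >= 0")
  if (thickness_mm <= 0) stop_validation("thickness_mm must be > 0")
  if (interval < 1) stop_validation("interval must be >= 1")
  if (shrinkage < 0) stop_validation("shrinkage must be >= 0")
  sum(section_areas) * thickness_mm * interval * shrinkage
}

#' Monte Carlo permutation test for a difference between two groups
#'
#' Two-sided test on the mean difference. Unpaired: group labels are
#' permuted over the pooled values. Paired (`paired = TRUE`, equal-length
#' groups): signs of the within-pair differences are flipped. The p-value
#' uses the add-one estimator `(1 + #extreme) / (n_perm + 1)` so it is never
#' exactly zero.
#'
#' @param a,b Numeric vectors (non-empty; equal length if paired).
#' @param n_perm Number of random permutations (>= 1000).
#' @param seed Optional RNG seed (deterministic given the seed).
#' @param paired Use sign-flipping of paired differences.
#' @return List: `p`, `observed` (mean difference a - b), `n_perm`.
#' @export
permutation_test <- function(a, b, n_perm = 10000, seed = NULL,
                             paired = FALSE) {
  if (!length(a) || !length(b)) stop_validation("both groups must be non-empty")
  if (n_perm < 1000) stop_validation("n_perm must be >= 1000")
  obs <- mean(a) - mean(b)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    warning("all pooled values identical; p = 1")
    return(list(p = 1, observed = obs, n_perm = as.integer(n_perm)))
  }
  p <- with_seed(seed, {
    if (paired) {
      if (length(a) != length(b)) {
        stop_validation("paired test requires equal group sizes")
      }
      d <- a - b
      signs <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE),
                      n_perm, length(d))
      stat <- abs(signs %*% d) / length(d)
      (1 + sum(stat >= abs(obs) - 1e-12)) / (n_perm + 1)
    } else {
      na <- length(a); n <- length(pooled)
      # sorting the pooled values makes the Monte Carlo draw invariant to
      # the group order (the permutation null only sees the pooled multiset)
      pooled_s <- sort(pooled)
      cnt <- 0L
      for (i in seq_len(n_perm)) {
        idx <- sample.int(n, na)
        s <- mean(pooled_s[idx]) - mean(pooled_s[-idx])
        if (abs(s) >= abs(obs) - 1e-12) cnt <- cnt + 1L
      }
      (1 + cnt) / (n_perm + 1)
    }
  })
  list(p = as.numeric(p), observed = obs, n_perm = as.integer(n_perm))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR adjustment of a vector of p-values with a significance mask
#' at level `q`. Adjusted p-values are monotone in rank and never below the
#' raw p-values.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @param q FDR level.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return List: `adjusted`, `significant` (logical), `q`, `method`.
#' @export
fdr_correct <- function(pvalues, q = 0.05, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (!length(pvalues)) {
    return(list(adjusted = numeric(0), significant = logical(0), q = q,
                method = method))
  }
  if (any(pvalues < 0 | pvalues > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  adj <- p.adjust(pvalues, method = method)
  list(adjusted = adj, significant = adj < q, q = q, method = method)
}

#' Build a volume table
#'
#' @param brain,hemisphere,gender,area Vectors of identifiers.
#' @param volume_mm3,whole_brain_volume_mm3 Volumes (mm^3).
#' @return `data.frame` of class `volume_table` with a `fraction` column
#'   (areal volume as fraction of whole-brain volume, the scale on which
#'   group comparisons are run).
#' @export
volume_table <- function(brain, hemisphere, gender, area, volume_mm3,
                         whole_brain_volume_mm3) {
  if (any(volume_mm3 < 0) || any(whole_brain_volume_mm3 <= 0)) {
    stop_validation("volumes must be >= 0 and whole-brain volumes > 0")
  }
  df <- data.frame(brain = as.character(brain),
                   hemisphere = as.character(hemisphere),
                   gender = as.character(gender),
                   area = as.character(area),
                   volume_mm3 = volume_mm3,
                   whole_brain_volume_mm3 = whole_brain_volume_mm3)
  df$fraction <- df$volume_mm3 / df$whole_brain_volume_mm3
  if (any(df$fraction > 1)) stop_validation("areal volume exceeds whole brain")
  class(df) <- c("volume_table", "data.frame")
  df
}

#' Compare areal volume fractions between hemispheres or genders
#'
#' Per area, a Monte Carlo permutation test on whole-brain volume fractions:
#' paired (sign-flip within brain, left minus right) for the hemisphere
#' factor, unpaired on per-brain mean fractions for the gender factor.
#' P-values are corrected across areas (FDR by default).
#'
#' @param table A [volume_table()].
#' @param factor `"hemisphere"` or `"gender"`.
#' @param n_perm Permutations per test (>= 1000).
#' @param seed Optional RNG seed.
#' @param q Significance level after correction.
#' @param method Correction method, see [fdr_correct()].
#' @return `data.frame`: per area `p`, `p_adjusted`, `significant`,
#'   `observed` (mean fraction difference).
#' @export
compare_volumes <- function(table, factor = c("hemisphere", "gender"),
                            n_perm = 10000, seed = NULL, q = 0.05,
                            method = c("BH", "bonferroni")) {
  factor <- match.arg(factor)
  method <- match.arg(method)
  stopifnot(inherits(table, "volume_table") || is.data.frame(table))
  if (is.null(table$fraction)) {
    if (is.null(table$whole_brain_volume_mm3)) {
      stop_validation("whole-brain volumes missing")
    }
    table$fraction <- table$volume_mm3 / table$whole_brain_volume_mm3
  }
  areas <- sort(unique(table$area))
  lv <- sort(unique(table[[factor]]))
  if (length(lv) != 2L) stop_validation("%s must have exactly 2 levels", factor)
  res <- lapply(seq_along(areas), function(i) {
    tab <- table[table$area == areas[i], ]
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed + i, "volumes")
    if (factor == "hemisphere") {
      wide <- merge(tab[tab$hemisphere == lv[1], c("brain", "fraction")],
                    tab[tab$hemisphere == lv[2], c("brain", "fraction")],
                    by = "brain")
      if (nrow(wide) < 2L) {
        stop_validation("need >= 2 brains with both hemispheres for area %s",
                        areas[i])
      }
      permutation_test(wide$fraction.x, wide$fraction.y, n_perm = n_perm,
                       seed = sub_seed, paired = TRUE)
    } else {
      per_brain <- aggregate(fraction ~ brain + gender, tab, mean)
      g1 <- per_brain$fraction[per_brain$gender == lv[1]]
      g2 <- per_brain$fraction[per_brain$gender == lv[2]]
      if (length(g1) < 2L || length(g2) < 2L) {
        stop_validation("need >= 2 brains per %s level for area %s", factor,
                        areas[i])
      }
      permutation_test(g1, g2, n_perm = n_perm, seed = sub_seed)
    }
  })
  p <- vapply(res, `[[`, 0, "p")
  corr <- fdr_correct(p, q = q, method = method)
  data.frame(area = areas, p = p, p_adjusted = corr$adjusted,
             significant = corr$significant,
             observed = vapply(res, `[[`, 0, "observed"))
}
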