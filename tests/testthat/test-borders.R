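test_that("feature vector matches the weighted-moment formulas", {
  # independent longhand evaluation, frozen to full precision
  fv <- profile_features(c(0.2, 0.4, 0.6, 0.8), depth = c(0, 1/3, 2/3, 1))
  expect_equal(unname(fv),
               c(0.5, 2/3, 1/3, -0.6, 2.2,
                 0.2, 0.5, 0.272165526975909, 0, 1.5),
               tolerance = 1e-12)
})

test_that("feature vector symmetry and degenerate profiles behave as specified", {
  # symmetric profile about depth 0.5: centroid 0.5, zero skewness
  x <- seq(0, 1, length.out = 101)
  y <- exp(-((x - 0.5) / 0.15)^2)
  fv <- profile_features(y, x)
  expect_equal(unname(fv["mean_x"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(fv["skew_x"]), 0, tolerance = 1e-10)
  # constant profile: uniform weights, flat derivative handled degenerately
  expect_warning(fc <- profile_features(rep(0.4, 101), x), "zero")
  expect_equal(unname(fc["mean_gli"]), 0.4)
  expect_equal(unname(fc["mean_x"]), 0.5)
  n <- 101
  expect_equal(unname(fc["sd_x"]),
               sqrt(mean((x - 0.5)^2)), tolerance = 1e-12)
  expect_equal(unname(fc["sd_x"]), 1 / sqrt(12), tolerance = 1e-2)
  expect_equal(unname(fc[c("d_mean", "d_sd_x", "d_skew_x", "d_kurt_x")]),
               c(0, 0, 0, 0))
  expect_error(profile_features(rep(0, 20)), "all-zero")
})

test_that("Mahalanobis distance is zero for identical blocks and affine invariant", {
  set.seed(5)
  base <- matrix(rnorm(12 * 10), 12, 10)
  fm <- rbind(base, base)  # two identical blocks
  mf <- md_function(fm, 12, features = TRUE)
  mid <- which(mf$positions == 12)
  expect_equal(mf$md[mid], 0, tolerance = 1e-7)
  # affine rescaling of all ten features leaves MD unchanged
  fm2 <- matrix(rnorm(80 * 10), 80, 10)
  scale_ <- runif(10, 0.2, 8)
  shift <- rnorm(10, sd = 5)
  fm2r <- sweep(sweep(fm2, 2, scale_, `*`), 2, shift, `+`)
  m1 <- md_function(fm2, 20, features = TRUE)
  m2 <- md_function(fm2r, 20, features = TRUE)
  expect_lt(max(abs(m1$md - m2$md)), 1e-8)
  expect_equal(m1$p_corrected, m2$p_corrected, tolerance = 1e-8)
})

test_that("Hotelling p-values are uniform under the multivariate null", {
  set.seed(17)
  pv <- replicate(500, {
    f <- matrix(rnorm(40 * 10), 40, 10)
    mf <- md_function(f, 20, features = TRUE)
    mf$p_raw[mf$positions == 20]
  })
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.03)
})

test_that("block size limits and singular covariance are enforced", {
  f <- matrix(rnorm(60 * 10), 60, 10)
  expect_error(md_function(f, 10, features = TRUE), "feature dimension")
  expect_error(md_function(f, 40, features = TRUE), "exceeds")
  # a constant feature column makes the pooled covariance singular
  set.seed(3)
  fc <- cbind(matrix(rnorm(40 * 9), 40, 9), 1)
  expect_error(md_function(fc, 15, features = TRUE), "singular")
  expect_silent(md_function(fc, 15, features = TRUE, shrinkage = 0.1))
  # fully degenerate blocks (identical means) are distance zero, not an error
  expect_equal(max(md_function(matrix(1, 40, 10), 15, features = TRUE)$md), 0)
})

test_that("peak MD does not decrease when the laminar contrast doubles", {
  fr <- c(0.1, 0.3, 0.3, 0.1, 0.2)
  base <- c(0.5, 0.4, 0.3, 0.5, 0.45)
  peak_md <- function(delta) {
    a <- laminar_model(fr, base, 0, "a")
    b2 <- base; b2[2] <- b2[2] + delta
    b <- laminar_model(fr, b2, 0, "b")
    # tiny fixed perturbation so covariances are non-singular, identical
    # across deltas: only the mean separation changes
    r <- render_ribbon(list(a, b), c(40, 40), seed = 99)
    set.seed(1)
    pert <- matrix(rnorm(80 * 100, sd = 1e-3), 80, 100)
    max(md_function(pmin(pmax(r$profiles + pert, 0), 1), 12)$md)
  }
  deltas <- c(0.05, 0.1, 0.2, 0.4)
  peaks <- vapply(deltas, peak_md, 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("a two-area ribbon yields a significant MD maximum at the true border", {
  m <- two_area_models(0.03)
  r <- render_ribbon(m, c(76, 86), seed = 12)
  mf <- md_function(r, 23)
  peak <- mf$positions[which.max(mf$md)]
  expect_lte(abs(peak - 76), 3)
  expect_lt(mf$p_corrected[which.max(mf$md)], 0.001)
})

test_that("border detection recovers ground truth and stays silent on noise", {
  m <- two_area_models(0.03)
  # noise-free single area: no borders
  quiet <- detect_borders(render_ribbon(list(two_area_models(0)[[1]]), 162,
                                        seed = 1))
  expect_length(quiet$borders, 0)
  # two-area ribbon: single border with broad block-size support
  bs <- detect_borders(render_ribbon(m, c(76, 86), seed = 2))
  expect_length(bs$borders, 1)
  expect_lte(abs(bs$borders - 76), 3)
  expect_gte(length(bs$support[[1]]), 5)
  sup <- bs$support[[1]]
  expect_true(any(diff(sup) == 1))  # consecutive block sizes agree
  # three areas: both borders, ten seeds
  m3 <- three_area_models(0.03)
  hits <- vapply(1:10, function(s) {
    b <- detect_borders(render_ribbon(m3, c(60, 60, 60), seed = 300 + s))
    length(b$borders) == 2 && all(abs(b$borders - c(60, 120)) <= 3)
  }, TRUE)
  expect_true(all(hits))
})

test_that("border positions mirror when the ribbon is reversed", {
  m <- two_area_models(0.03)
  r <- render_ribbon(m, c(76, 86), seed = 5)
  fwd <- detect_borders(r)$borders
  rev_ <- detect_borders(r$profiles[nrow(r$profiles):1, ])$borders
  expect_length(rev_, length(fwd))
  # mirrored up to the one-traverse asymmetry of plateau-midpoint rounding
  expect_lte(max(abs(sort(rev_) - sort(162L - fwd))), 1)
})

test_that("alpha and block-range validation", {
  m <- two_area_models(0.03)
  r <- render_ribbon(m, c(20, 20), seed = 1)
  expect_error(detect_borders(r, alpha = 0), "alpha")
  expect_error(detect_borders(r, block_range = c(30, 40)), "admissible")
})
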