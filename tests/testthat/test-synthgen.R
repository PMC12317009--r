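test_that("laminar model validation catches malformed inputs", {
  expect_error(laminar_model(c(0.5, 0.6), c(0.4, 0.4)), "sum to 1")
  expect_error(laminar_model(c(0.5, 0.5), c(0.4, 1.2)), "\\[0, 1\\]")
  expect_error(laminar_model(c(0.5, 0.5), c(0.4, 0.4), noise_sd = -1), "noise_sd")
  expect_error(laminar_model(c(0.5, -0.5, 1), c(0.1, 0.2, 0.3)), "positive")
  m <- laminar_model(1, 0.5)
  expect_equal(model_profile(m, 50), rep(0.5, 50))
  m5 <- laminar_model(c(0.1, 0.3, 0.3, 0.1, 0.2),
                      c(0.6, 0.4, 0.3, 0.5, 0.45))
  expect_s3_class(m5, "laminar_model")
  expect_length(model_profile(m5, 100), 100)
})

test_that("ribbon rendering is deterministic and carries ground truth", {
  m <- two_area_models(0.03)
  r1 <- render_ribbon(m, c(80, 82), seed = 7)
  r2 <- render_ribbon(m, c(80, 82), seed = 7)
  expect_identical(r1, r2)
  expect_identical(r1$true_borders, 80L)
  expect_identical(unique(r1$area_labels[1:80]), "agranular")
  expect_identical(unique(r1$area_labels[81:162]), "dysgranular")
  expect_true(all(r1$profiles >= 0 & r1$profiles <= 1))
  expect_error(render_ribbon(m, c(80, 82, 10)), "equal length")
})

test_that("single noise-free model gives identical profiles and no borders", {
  m <- laminar_model(c(0.3, 0.7), c(0.5, 0.2), noise_sd = 0)
  r <- render_ribbon(m, 40, seed = 1)
  expect_length(r$true_borders, 0)
  expect_equal(max(apply(r$profiles, 2, var)), 0)
  expect_true(all(r$profiles == rep(model_profile(m, 100), each = 40)))
})

test_that("segment mean difference matches the laminar model contrast", {
  # models differ by exactly 0.2 in the density of layer 2 (depth 0.1-0.4)
  a <- laminar_model(c(0.1, 0.3, 0.6), c(0.5, 0.3, 0.4), 0.02, "a")
  b <- laminar_model(c(0.1, 0.3, 0.6), c(0.5, 0.5, 0.4), 0.02, "b")
  r <- render_ribbon(list(a, b), c(120, 120), depth_bins = 100, seed = 42)
  bins <- 11:40  # layer-2 depth bins
  diff_mean <- mean(colMeans(r$profiles[121:240, bins]) -
                      colMeans(r$profiles[1:120, bins]))
  sem <- 0.02 / sqrt(120 * length(bins))
  expect_lt(abs(diff_mean - 0.2), 3 * sem)
})

test_that("flat cell image renders the requested foreground density", {
  m <- laminar_model(1, 0.5)
  im <- render_gli_image(list(m), segment_px = 400, thickness_px = 80,
                         seed = 5)
  expect_identical(dim(im$image), c(80L, 400L))
  frac <- mean(im$image)
  expect_lt(abs(frac - 0.5), 0.02)
  im2 <- render_gli_image(list(m), segment_px = 400, thickness_px = 80,
                          seed = 5)
  expect_identical(im$image, im2$image)
  zero <- render_gli_image(list(laminar_model(1, 0)), 200, 80, seed = 1)
  expect_true(all(zero$image == 0L))
})

test_that("curved geometry rejects self-intersecting contours", {
  m <- laminar_model(1, 0.5)
  expect_error(render_gli_image(list(m), 200, thickness_px = 100,
                                curvature = 1 / 80),
               "self-intersect")
  ok <- render_gli_image(list(m), 200, thickness_px = 64,
                         curvature = 1 / 500, seed = 2)
  expect_true(mean(ok$image[ok$image >= 0]) >= 0)  # renders without error
  expect_equal(nrow(ok$outer), nrow(ok$inner))
})

test_that("subject label sets honour jitter and determinism", {
  shape <- c(32, 16, 16)
  layout <- demo_area_layout(shape, c("A1", "A2"), 5)
  aff <- diag(c(1, 1, 1, 1))
  s0 <- make_subject_labelsets(shape, aff, layout, n_subjects = 4,
                               jitter_mm = 0, seed = 3)
  for (v in s0$volumes) expect_identical(v$grid, s0$canonical$grid)
  s1 <- make_subject_labelsets(shape, aff, layout, n_subjects = 6,
                               jitter_mm = 2, seed = 9)
  s2 <- make_subject_labelsets(shape, aff, layout, n_subjects = 6,
                               jitter_mm = 2, seed = 9)
  expect_identical(lapply(s1$volumes, `[[`, "grid"),
                   lapply(s2$volumes, `[[`, "grid"))
  expect_false(all(s1$volumes[[1]]$grid == s1$volumes[[2]]$grid))
  # overlapping canonical masks are rejected
  bad <- layout
  bad$A2 <- bad$A1
  expect_error(make_subject_labelsets(shape, aff, bad, 2, 1, 1), "disjoint")
  # extreme jitter clips labels with a warning
  expect_warning(
    make_subject_labelsets(shape, aff, layout, n_subjects = 8,
                           jitter_mm = 30, seed = 4),
    "clipped")
})

test_that("synthetic volume tables are reproducible with valid fractions", {
  t1 <- synth_volume_table(seed = 11)
  t2 <- synth_volume_table(seed = 11)
  expect_identical(t1, t2)
  expect_true(all(t1$fraction > 0 & t1$fraction < 1))
  expect_identical(nrow(t1), 10L * 2L * 7L)
  te <- synth_volume_table(effect_area = "ar2", effect_sd = 5, seed = 11)
  sel_l <- te$area == "ar2" & te$hemisphere == "L"
  sel_r <- te$area == "ar2" & te$hemisphere == "R"
  expect_gt(mean(te$fraction[sel_l]) - mean(te$fraction[sel_r]), 3e-4 * 3)
})
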