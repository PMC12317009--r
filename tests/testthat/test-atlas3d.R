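test_that("pmaps count subject labels exactly", {
  shape <- c(24, 12, 12)
  layout <- demo_area_layout(shape, c("A1", "A2"), 4)
  aff <- diag(c(2, 2, 2, 1))
  ss <- make_subject_labelsets(shape, aff, layout, n_subjects = 10,
                               jitter_mm = 0, seed = 2)
  pm <- build_pmap(ss$volumes, "A1")
  expect_true(all(pm$grid %in% c(0, 1)))  # identical subjects: binary pmap
  # jittered subjects: brute-force per-voxel recount oracle
  ssj <- make_subject_labelsets(shape, aff, layout, n_subjects = 10,
                                jitter_mm = 2, seed = 1)
  pmj <- build_pmap(ssj$volumes, "A2")
  lab <- ssj$vocabulary[["A2"]]
  recount <- array(0, shape)
  for (v in ssj$volumes) {
    for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
      for (k in seq_len(shape[3])) {
        recount[i, j, k] <- recount[i, j, k] + (v$grid[i, j, k] == lab)
      }
  }
  expect_equal(pmj$grid, recount / 10)
  expect_true(all(abs(pmj$grid * 10 - round(pmj$grid * 10)) < 1e-9))
  # affine mismatch is an error, not a silent resample
  v2 <- ssj$volumes
  v2[[2]]$affine[1, 4] <- 5
  expect_error(build_pmap(v2, "A1"), "co-register")
})

test_that("centre of gravity is the intensity-weighted world mean", {
  aff <- diag(c(1, 1, 1, 1))
  g <- array(0, c(10, 10, 10))
  g[3, 4, 5] <- 0.7
  pm <- structure(list(grid = g, affine = aff, area = "x", n_subjects = 10),
                  class = "probability_map")
  expect_equal(unname(centre_of_gravity(pm)), c(2, 3, 4))  # 0-based voxel
  # two voxels with weights 0.2 and 0.6 at x = 0 and x = 4
  g2 <- array(0, c(10, 4, 4))
  g2[1, 1, 1] <- 0.2; g2[5, 1, 1] <- 0.6
  pm2 <- structure(list(grid = g2, affine = aff), class = "probability_map")
  expect_equal(unname(centre_of_gravity(pm2))[1], 3)
  # uniform cube: geometric centre
  g3 <- array(0, c(9, 9, 9)); g3[3:5, 3:5, 3:5] <- 0.5
  pm3 <- structure(list(grid = g3, affine = aff), class = "probability_map")
  expect_equal(unname(centre_of_gravity(pm3)), c(3, 3, 3))
  # equivariance under affine translation
  aff2 <- aff; aff2[1:3, 4] <- c(10, -5, 2)
  pm4 <- pm3; pm4$affine <- aff2
  expect_equal(unname(centre_of_gravity(pm4)),
               c(3, 3, 3) + c(10, -5, 2))
  pm0 <- pm3; pm0$grid[] <- 0
  expect_error(centre_of_gravity(pm0), "all-zero")
})

test_that("MPM equals the independent voxelwise rule on random families", {
  for (s in 1:6) {
    fam <- random_pmap_family(n_areas = 3, dims = c(12, 10, 8), seed = s)
    mpm <- build_mpm(fam)
    expect_identical(mpm$grid, naive_mpm(fam))
    # partition property: every suprathreshold voxel carries one label and
    # has a contributing pmap
    nz <- which(mpm$grid > 0)
    for (a in seq_along(fam)) {
      sel <- which(mpm$grid == a)
      if (length(sel)) expect_true(all(fam[[a]]$grid[sel] > 0))
    }
  }
})

test_that("MPM tie-breaking uses the neighbourhood mean and the 40% rule", {
  d <- c(5, 5, 5)
  aff <- diag(4)
  ga <- array(0, d); gb <- array(0, d)
  ga[3, 3, 3] <- 0.5; gb[3, 3, 3] <- 0.5            # exact tie at centre
  ga[2:4, 2:4, 2] <- 0.5                             # A-rich neighbourhood
  gb[3, 3, 4] <- 0.3
  fam <- list(
    A = structure(list(grid = ga, affine = aff, area = "A", n_subjects = 10),
                  class = "probability_map"),
    B = structure(list(grid = gb, affine = aff, area = "B", n_subjects = 10),
                  class = "probability_map"))
  mpm <- build_mpm(fam)
  expect_identical(mpm$grid[3, 3, 3], 1L)  # A wins the tie by neighbour mean
  expect_identical(mpm$n_ties, 1L)
  # isolated voxel with a single area below threshold stays unassigned
  expect_identical(mpm$grid[3, 3, 4], 0L)  # B alone at 0.3 < 0.4
  # but suprathreshold solitary voxels are kept
  expect_identical(mpm$grid[2, 2, 2], 1L)  # A alone at 0.5 >= 0.4
  # sub-threshold winner with a mapped competitor is kept
  ga2 <- array(0, d); gb2 <- array(0, d)
  ga2[1, 1, 1] <- 0.3; gb2[1, 1, 1] <- 0.2
  fam2 <- list(
    A = structure(list(grid = ga2, affine = aff, area = "A"),
                  class = "probability_map"),
    B = structure(list(grid = gb2, affine = aff, area = "B"),
                  class = "probability_map"))
  expect_identical(build_mpm(fam2)$grid[1, 1, 1], 1L)
})

test_that("map correlation matches the direct formula and its invariances", {
  fam <- random_pmap_family(2, dims = c(16, 16, 16), seed = 9)
  a <- fam[[1]]; b <- fam[[2]]
  expect_equal(correlate_maps(a, a), 1)
  r <- correlate_maps(a, b)
  expect_equal(r, correlate_maps(b, a))
  # direct formula over the union domain
  mask <- a$grid > 0 | b$grid > 0
  x <- a$grid[mask]; y <- b$grid[mask]
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, direct, tolerance = 1e-12)
  # scale invariance
  a2 <- a; a2$grid <- a$grid * 0.5
  expect_equal(correlate_maps(a2, b), r, tolerance = 1e-12)
  # binary map vs its complement over the full grid: perfect anticorrelation
  bin <- a; bin$grid <- (a$grid > 0.2) * 1
  inv <- a; inv$grid <- 1 - bin$grid
  full <- array(TRUE, dim(a$grid))
  expect_equal(correlate_maps(bin, inv, mask = full), -1)
  flat <- a; flat$grid[] <- 0.4
  expect_error(correlate_maps(flat, b, mask = full), "variance")
})

test_that("coordinates are assigned to areas above the probability threshold", {
  d <- c(10, 10, 10)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-10, -10, -10)
  ga <- array(0, d); gb <- array(0, d)
  ga[5, 5, 5] <- 1.0
  ga[2, 2, 2] <- 0.3; gb[2, 2, 2] <- 0.1
  fam <- list(
    A = structure(list(grid = ga, affine = aff, area = "A"),
                  class = "probability_map"),
    B = structure(list(grid = gb, affine = aff, area = "B"),
                  class = "probability_map"))
  core <- as.numeric(aff %*% c(4, 4, 4, 1))[1:3]
  r1 <- assign_coordinate(core, fam)
  expect_identical(r1$area, "A")
  expect_equal(r1$probability, 1.0)
  r2 <- assign_coordinate(as.numeric(aff %*% c(1, 1, 1, 1))[1:3], fam)
  expect_identical(r2$area, "A")  # B at 0.1 < 0.2 suppressed
  expect_warning(r3 <- assign_coordinate(c(500, 0, 0), fam), "outside")
  expect_identical(nrow(r3), 0L)
  # batch lookup equals brute-force indexing
  set.seed(2)
  vox <- cbind(sample(0:9, 20, TRUE), sample(0:9, 20, TRUE),
               sample(0:9, 20, TRUE))
  for (i in 1:20) {
    xyz <- as.numeric(aff %*% c(vox[i, ], 1))[1:3]
    got <- assign_coordinate(xyz, fam, threshold = 0)
    pa <- ga[vox[i, 1] + 1, vox[i, 2] + 1, vox[i, 3] + 1]
    pb <- gb[vox[i, 1] + 1, vox[i, 2] + 1, vox[i, 3] + 1]
    expect_equal(sum(got$probability), pa + pb)
  }
})
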