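test_that("area mean feature vectors average sampled profiles", {
  m <- laminar_model(c(0.3, 0.7), c(0.6, 0.3), 0, "flat")
  secs <- lapply(1:3, function(i) render_ribbon(m, 50, seed = i))
  # noise-free two-layer profiles have a single-point derivative, so the
  # degenerate-moment warning is expected here
  fv <- suppressWarnings(mean_area_feature(secs, 45, seed = 1))
  # noise-free: every profile identical, mean equals the single vector
  single <- suppressWarnings(
    profile_features(model_profile(m, 100), depth = (1:100 - 0.5) / 100))
  expect_equal(fv, single, tolerance = 1e-12)
  # insufficient profiles is an error
  short <- lapply(1:3, function(i) render_ribbon(m, 44, seed = i))
  expect_error(mean_area_feature(short, 45), "44 < 45")
  # identical-distribution sections: two seeds agree within sampling error
  mn <- laminar_model(c(0.3, 0.7), c(0.6, 0.3), 0.02, "noisy")
  secs2 <- lapply(1:3, function(i) render_ribbon(mn, 300, seed = 10 + i))
  f1 <- mean_area_feature(secs2, 45, seed = 101)
  f2 <- mean_area_feature(secs2, 45, seed = 202)
  expect_lt(max(abs(f1 - f2) / (abs(f1) + 1e-3)), 0.1)
})

test_that("Euclidean distance matrix matches the brute-force double loop", {
  expect_equal(distance_matrix(rbind(a = c(0, 0, 0, 0), b = c(3, 4, 0, 0)))["a", "b"],
               5)
  x <- rbind(a = 1:10, b = 1:10)
  expect_equal(distance_matrix(x)["a", "b"], 0)
  set.seed(14)
  tab <- matrix(rnorm(8 * 10), 8, 10,
                dimnames = list(paste0("ar", 1:8), NULL))
  D <- distance_matrix(tab)
  for (i in 1:8) for (j in 1:8) {
    expect_equal(D[i, j], sqrt(sum((tab[i, ] - tab[j, ])^2)),
                 tolerance = 1e-12)
  }
  expect_equal(D, t(D))
  # label-order invariance up to permutation
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  D2 <- distance_matrix(tab[perm, ])
  expect_equal(D2, D[perm, perm])
  expect_error(distance_matrix(rbind(c(1, NA), c(0, 1))), "finite")
})

test_that("metric MDS recovers exactly embeddable configurations", {
  set.seed(3)
  pts <- cbind(rnorm(5), rnorm(5))
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- letters[1:5]
  e <- mds_embed(D, 2, n_restarts = 4, seed = 1)
  expect_lt(e$stress, 1e-6)
  expect_lt(max(abs(as.matrix(dist(e$points)) - D)), 1e-6)
  expect_equal(colMeans(e$points), c(0, 0), tolerance = 1e-9)
  # stress is invariant under rotation/reflection of the configuration
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- e$points %*% R
  expect_equal(cytoarch:::stress1(rot, D), e$stress, tolerance = 1e-12)
  expect_equal(cytoarch:::stress1(e$points %*% diag(c(-1, 1)), D), e$stress,
               tolerance = 1e-12)
})

test_that("MDS stress on the unit 3-simplex matches the independent optimum", {
  # 4 points, all pairwise distances 1, forced into the plane; the optimal
  # stress-1 was computed by direct numerical minimization (BFGS restarts)
  D <- matrix(1, 4, 4) - diag(4)
  dimnames(D) <- list(letters[1:4], letters[1:4])
  e <- mds_embed(D, 2, n_restarts = 8, seed = 3)
  expect_equal(e$stress, 0.169102, tolerance = 1e-3)
  expect_error(mds_embed(D, dims = 4), "dims")
})

test_that("UPGMA reproduces hand-worked merges and ultrametric input", {
  # two taxa at distance 4: single merge at height 2
  D2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- upgma_tree(D2)
  expect_equal(t2$height, 2)
  expect_match(t2$newick, "a:2")
  expect_match(t2$newick, "b:2")
  # three taxa: (A,B) first at height 1, C joins at height 3
  D3 <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma_tree(D3)
  expect_equal(t3$height, c(1, 3))
  expect_equal(cophenetic_distances(t3), D3)
  # heights are non-decreasing (ultrametricity)
  set.seed(4)
  x <- matrix(rnorm(7 * 3), 7, 3, dimnames = list(paste0("t", 1:7), NULL))
  tr <- upgma_tree(as.matrix(dist(x)))
  expect_true(all(diff(tr$height) >= -1e-12))
})

test_that("UPGMA equals naive enumeration and average-linkage hclust, n <= 6", {
  # oracle 1: naive UPGMA from helper-fixtures.R (exhaustive pair search on
  # the original matrix, no proportional update formula)
  set.seed(6)
  for (n in 3:6) for (rep in 1:5) {
    x <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(paste0("t", seq_len(n)), NULL))
    D <- as.matrix(dist(x))
    tr <- upgma_tree(D)
    expect_equal(tr$height, naive_upgma_heights(D), tolerance = 1e-10)
    # oracle 2: hclust average linkage (heights are merge distances)
    hc <- hclust(as.dist(D), method = "average")
    expect_equal(tr$height, hc$height / 2, tolerance = 1e-10)
    # cophenetic distances: mine are 2 * height = merge distance, which is
    # exactly hclust's cophenetic value
    expect_equal(cophenetic_distances(tr)[tr$labels, tr$labels],
                 as.matrix(cophenetic(hc))[tr$labels, tr$labels],
                 tolerance = 1e-10)
  }
})

test_that("Newick export round-trips through ape with correct heights", {
  skip_if_not_installed("ape")
  set.seed(9)
  x <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(paste0("t", 1:6), NULL))
  D <- as.matrix(dist(x))
  tr <- upgma_tree(D)
  ph <- ape::read.tree(text = tr$newick)
  expect_setequal(ph$tip.label, rownames(D))
  coph <- cophenetic_distances(tr)
  ape_coph <- ape::cophenetic.phylo(ph)
  expect_equal(ape_coph[rownames(coph), colnames(coph)], coph,
               tolerance = 1e-8)
})

test_that("distinct laminar families split into two clusters", {
  split_ok <- vapply(1:10, function(s) {
    D <- distance_matrix(two_family_features(s))
    grp <- cut_upgma(upgma_tree(D), 2)
    topo <- length(unique(grp[1:4])) == 1 && length(unique(grp[5:8])) == 1 &&
      grp[1] != grp[5]
    emb <- mds_embed(D, 2, n_restarts = 4, seed = s)
    within <- mean(dist(emb$points[1:4, ])) + mean(dist(emb$points[5:8, ]))
    between <- mean(as.matrix(dist(emb$points))[1:4, 5:8])
    topo && between > within / 2
  }, TRUE)
  expect_true(all(split_ok))
})
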