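# Shared synthetic fixtures. Everything is generated in code, seeded.

two_area_models <- function(noise_sd = 0.03) {
  default_laminar_models(noise_sd = noise_sd)
}

three_area_models <- function(noise_sd = 0.03) {
  m <- default_laminar_models(noise_sd = noise_sd)
  m$granular <- laminar_model(c(0.15, 0.25, 0.30, 0.10, 0.20),
                              c(0.45, 0.40, 0.50, 0.35, 0.60),
                              noise_sd, "granular")
  m
}

# random aligned pmap family on a small grid; probabilities are multiples
# of 1/n_subjects as produced by counting subjects
random_pmap_family <- function(n_areas = 3, dims = c(20, 20, 20),
                               n_subjects = 10, seed = 1) {
  set.seed(seed)
  affine <- diag(c(1, 1, 1, 1))
  lapply(setNames(seq_len(n_areas), paste0("A", seq_len(n_areas))),
         function(a) {
    counts <- array(rbinom(prod(dims), n_subjects, 0.25), dims)
    structure(list(grid = counts / n_subjects, affine = affine,
                   area = paste0("A", a), n_subjects = n_subjects),
              class = "probability_map")
  })
}

# independent per-voxel reimplementation of the MPM rule (argmax, neighbour
# -mean tie-break, threshold where no competitor is mapped): plain loops,
# no shared code with build_mpm
naive_mpm <- function(pmaps, threshold = 0.4) {
  d <- dim(pmaps[[1]]$grid)
  out <- array(0L, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- vapply(pmaps, function(m) m$grid[i, j, k], 0)
    if (max(p) == 0) next
    win <- which(p == max(p))
    if (length(win) > 1L) {
      nbm <- vapply(win, function(a) {
        acc <- c()
        for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
          if (di == 0 && dj == 0 && dk == 0) next
          ii <- i + di; jj <- j + dj; kk <- k + dk
          if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
              kk >= 1 && kk <= d[3]) {
            acc <- c(acc, pmaps[[a]]$grid[ii, jj, kk])
          }
        }
        mean(acc)
      }, 0)
      win <- win[which.max(nbm)]
    } else if (max(p) < threshold && sum(p > 0) == 1L) {
      next
    }
    out[i, j, k] <- win[1]
  }
  out
}

expect_no_warning <- function(expr) expect_warning(expr, regexp = NA)

# naive UPGMA oracle: recomputes unweighted leaf-pair mean distances from the
# original matrix at every step (exhaustive pair search, no update formula)
naive_upgma_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dm <- mean(D[clusters[[i]], clusters[[j]]])
      if (dm < best - 1e-12) { best <- dm; bi <- i; bj <- j }
    }
    heights <- c(heights, best / 2)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# eight synthetic areas from two laminar families; returns their labelled
# feature-vector matrix (4 areas per family)
two_family_features <- function(seed) {
  fr <- c(0.1, 0.3, 0.3, 0.1, 0.2)
  fam_a <- c(0.60, 0.40, 0.30, 0.50, 0.45)
  fam_b <- c(0.45, 0.55, 0.50, 0.30, 0.60)
  set.seed(seed)
  vecs <- t(sapply(1:8, function(i) {
    base <- if (i <= 4) fam_a else fam_b
    m <- laminar_model(fr, pmin(pmax(base + rnorm(5, 0, 0.02), 0), 1),
                       0.02, paste0("a", i))
    secs <- lapply(1:3, function(k) {
      render_ribbon(m, 50, seed = seed * 100 + i * 10 + k)
    })
    mean_area_feature(secs, 45, seed = seed * 100 + i)
  }))
  rownames(vecs) <- paste0("a", 1:8)
  vecs
}
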