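same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$grid), dim(b$grid)) && max(abs(a$affine - b$affine)) <= tol
}

#' Build a probability map of one area from subject label volumes
#'
#' The probability map (pmap) records, per voxel, the fraction of subjects
#' in which the voxel carries the area's label: the probability that the
#' area occurs at that position of the reference space.
#'
#' @param volumes List of [label_volume()] objects sharing shape and affine
#'   (no resampling is performed; a mismatch is an error).
#' @param area Area name (must be in every volume's vocabulary).
#' @return Object of class `probability_map`: `grid` (fractions, multiples
#'   of `1/n_subjects`), `affine`, `area`, `n_subjects`.
#' @export
build_pmap <- function(volumes, area) {
  stopifnot(length(volumes) >= 1L)
  for (v in volumes[-1]) {
    if (!same_geometry(volumes[[1]], v)) {
      stop_validation("label volumes differ in shape or affine; co-register first")
    }
  }
  counts <- array(0, dim(volumes[[1]]$grid))
  for (v in volumes) {
    lab <- v$vocabulary[[area]]
    if (is.null(lab)) stop_validation("area '%s' not in vocabulary", area)
    counts <- counts + (v$grid == lab)
  }
  structure(list(grid = counts / length(volumes),
                 affine = volumes[[1]]$affine, area = area,
                 n_subjects = length(volumes)),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map '%s': %s grid, n = %d, %d nonzero voxels>\n",
              x$area, paste(dim(x$grid), collapse = "x"), x$n_subjects,
              sum(x$grid > 0)))
  invisible(x)
}

# world coordinates (mm) of 0-based voxel indices under a 4x4 affine
voxel_to_world <- function(idx0, affine) {
  h <- cbind(idx0, 1)
  t(affine %*% t(h))[, 1:3, drop = FALSE]
}

world_to_voxel <- function(xyz, affine) {
  h <- c(as.numeric(xyz), 1)
  as.numeric(solve(affine, h))[1:3]
}

#' Centre of gravity of a probability map
#'
#' Intensity-weighted mean of the world (mm) coordinates of all voxels with
#' non-zero probability; each voxel's probability serves as its weight.
#'
#' @param pmap A [build_pmap()] result.
#' @return Numeric xyz (mm).
#' @export
centre_of_gravity <- function(pmap) {
  nz <- which(pmap$grid > 0, arr.ind = TRUE)
  if (!nrow(nz)) stop_validation("all-zero probability map")
  w <- pmap$grid[nz]
  xyz <- voxel_to_world(nz - 1L, pmap$affine)
  colSums(xyz * w) / sum(w)
}

neighbour_offsets <- function(connectivity = 26) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  manh <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = manh == 1, "18" = manh <= 2, "26" = manh <= 3,
                 stop_validation("connectivity must be 6, 18 or 26"))
  as.matrix(g[keep, ])
}

# mean pmap value over the in-grid neighbourhood of a voxel (excluding it)
neighbour_mean <- function(grid, vox, offsets) {
  nb <- sweep(offsets, 2L, vox, `+`)
  d <- dim(grid)
  ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
    nb[, 3] >= 1 & nb[, 3] <= d[3]
  if (!any(ok)) return(0)
  mean(grid[nb[ok, , drop = FALSE]])
}

#' Build a maximum probability map from a family of probability maps
#'
#' Each voxel is assigned to the area with the highest probability. Voxels
#' where two or more areas tie are assigned to the tied area with the
#' highest mean probability over the voxel's neighbourhood (26-connectivity
#' by default, centre excluded); a tie surviving that rule falls to the
#' lowest area index and is counted. At borders where no competing area is
#' mapped (every other area has zero probability at the voxel) the
#' assignment is thresholded: a winning probability below
#' `unmapped_threshold` leaves the voxel unassigned (label 0).
#'
#' @param pmaps Named list of aligned [build_pmap()] results.
#' @param unmapped_threshold Threshold in \[0, 1\] applied where no mapped
#'   competitor exists (default 0.4).
#' @param connectivity Tie-break neighbourhood: 6, 18 or 26.
#' @return Object of class `mpm_volume`: `grid` (integer labels, 0 =
#'   unassigned), `affine`, `vocabulary`, `threshold`, `n_ties`,
#'   `n_unresolved_ties`.
#' @export
build_mpm <- function(pmaps, unmapped_threshold = 0.4, connectivity = 26) {
  stopifnot(length(pmaps) >= 1L)
  if (is.null(names(pmaps)) || any(names(pmaps) == "")) {
    names(pmaps) <- vapply(pmaps, `[[`, "", "area")
  }
  if (unmapped_threshold < 0 || unmapped_threshold > 1) {
    stop_validation("unmapped_threshold must be in [0, 1]")
  }
  for (p in pmaps[-1]) {
    if (!same_geometry(pmaps[[1]], p)) stop_validation("probability maps not aligned")
  }
  d <- dim(pmaps[[1]]$grid)
  na <- length(pmaps)
  P <- vapply(pmaps, function(p) as.vector(p$grid), numeric(prod(d)))
  P <- matrix(P, ncol = na)
  pmax_v <- do.call(pmax, lapply(seq_len(na), function(j) P[, j]))
  win <- max.col(P, ties.method = "first")
  is_tie <- rowSums(P == pmax_v) > 1L & pmax_v > 0
  offsets <- neighbour_offsets(connectivity)
  n_unresolved <- 0L
  if (any(is_tie)) {
    tie_idx <- which(is_tie)
    ai <- arrayInd(tie_idx, d)
    for (t in seq_along(tie_idx)) {
      v <- tie_idx[t]
      tied <- which(P[v, ] == pmax_v[v])
      nm <- vapply(tied, function(j) {
        neighbour_mean(pmaps[[j]]$grid, ai[t, ], offsets)
      }, 0)
      best <- tied[nm == max(nm)]
      if (length(best) > 1L) n_unresolved <- n_unresolved + 1L
      win[v] <- best[1L]
    }
  }
  labels <- win
  labels[pmax_v == 0] <- 0L
  # 40% threshold only where no mapped competitor exists at the voxel
  n_nonzero <- rowSums(P > 0)
  unmapped_border <- pmax_v > 0 & pmax_v < unmapped_threshold & n_nonzero == 1L
  labels[unmapped_border] <- 0L
  vocab <- setNames(seq_len(na), names(pmaps))
  structure(list(grid = array(as.integer(labels), d),
                 affine = pmaps[[1]]$affine, vocabulary = vocab,
                 threshold = unmapped_threshold,
                 n_ties = sum(is_tie), n_unresolved_ties = n_unresolved),
            class = "mpm_volume")
}

#' @export
print.mpm_volume <- function(x, ...) {
  cat(sprintf("<mpm_volume: %s grid, %d areas, %d assigned voxels, %d ties (%d unresolved)>\n",
              paste(dim(x$grid), collapse = "x"), length(x$vocabulary),
              sum(x$grid > 0), x$n_ties, x$n_unresolved_ties))
  invisible(x)
}

#' 3D correlation of two probability maps
#'
#' Pearson correlation of voxel values over a domain, quantifying the
#' spatial similarity of two areas: +1 for maps that vary together
#' identically through 3D space, 0 for independent maps, -1 for perfectly
#' opposed maps. The default domain is the union of both maps' non-zero
#' voxels.
#'
#' @param map_a,map_b Aligned [build_pmap()] results (or objects with `grid`
#'   and `affine`).
#' @param mask Optional logical array; default union of non-zero voxels.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
correlate_maps <- function(map_a, map_b, mask = NULL) {
  if (!same_geometry(map_a, map_b)) stop_validation("maps not aligned")
  if (is.null(mask)) mask <- map_a$grid > 0 | map_b$grid > 0
  if (!any(mask)) stop_validation("empty correlation domain")
  a <- map_a$grid[mask]; b <- map_b$grid[mask]
  if (sd(a) == 0 || sd(b) == 0) {
    stop_validation("zero variance over the domain; correlation undefined")
  }
  cor(a, b)
}

#' Assign a stereotaxic coordinate to cytoarchitectonic areas
#'
#' Looks up a world coordinate (mm) in a family of probability maps and
#' returns every area whose probability at the containing voxel reaches the
#' threshold (default p = 0.2), ordered by descending probability. A
#' coordinate outside the grid returns an empty assignment with a warning
#' (it cannot be localised within any pmap).
#'
#' @param xyz_mm Numeric xyz world coordinate (mm).
#' @param pmaps Named list of aligned probability maps.
#' @param threshold Minimum probability for reporting an area.
#' @return `data.frame` with columns `area`, `probability`, descending.
#' @export
assign_coordinate <- function(xyz_mm, pmaps, threshold = 0.2) {
  stopifnot(length(xyz_mm) == 3L, length(pmaps) >= 1L)
  if (is.null(names(pmaps)) || any(names(pmaps) == "")) {
    names(pmaps) <- vapply(pmaps, `[[`, "", "area")
  }
  d <- dim(pmaps[[1]]$grid)
  vox <- round(world_to_voxel(xyz_mm, pmaps[[1]]$affine)) + 1
  if (any(vox < 1) || any(vox > d)) {
    warning("coordinate outside the volume; not localised within any pmap")
    return(data.frame(area = character(0), probability = numeric(0)))
  }
  pr <- vapply(pmaps, function(p) p$grid[vox[1], vox[2], vox[3]], 0)
  keep <- pr >= threshold
  out <- data.frame(area = names(pmaps)[keep], probability = unname(pr[keep]))
  out[order(-out$probability), , drop = FALSE]
}

#' Volume of each labelled area in an MPM or label volume
#'
#' @param x `mpm_volume` or `label_volume`.
#' @return Named numeric vector of volumes (mm^3) per area.
#' @export
label_volumes_mm3 <- function(x) {
  vox_mm3 <- abs(det(x$affine[1:3, 1:3]))
  counts <- table(factor(x$grid[x$grid != 0L], levels = x$vocabulary,
                         labels = names(x$vocabulary)))
  setNames(as.numeric(counts) * vox_mm3, names(counts))
}
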