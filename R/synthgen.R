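#' Define a synthetic laminar model
#'
#' A laminar model describes one cortical area as a stack of layers, each
#' with a relative width (fraction of the cortical depth) and a mean cell
#' packing density expressed on the Grey Level Index (GLI) scale, i.e. as a
#' fraction in \[0, 1\]. Rendered profiles are the layer-density step
#' function over normalized depth, optionally smoothed to mimic gradual
#' laminar transitions, plus i.i.d. Gaussian noise clipped to \[0, 1\].
#'
#' @param layer_fractions Numeric vector of relative layer widths; must be
#'   positive and sum to 1.
#' @param layer_densities Numeric vector of per-layer mean GLI values in
#'   \[0, 1\]; same length as `layer_fractions`.
#' @param noise_sd Standard deviation of the additive Gaussian GLI noise
#'   (>= 0).
#' @param name Area label carried through to ground truth.
#' @param smooth Moving-average half-width, in depth bins, applied to the
#'   rendered step function (0 = no smoothing).
#' @return An object of class `laminar_model`.
#' @examples
#' m <- laminar_model(c(0.1, 0.3, 0.3, 0.1, 0.2),
#'                    c(0.6, 0.4, 0.3, 0.5, 0.45), noise_sd = 0.03,
#'                    name = "agranular-like")
#' plot(model_profile(m, 100), type = "l")
#' @export
laminar_model <- function(layer_fractions, layer_densities, noise_sd = 0,
                          name = "area", smooth = 0) {
  if (length(layer_fractions) != length(layer_densities)) {
    stop_validation("layer_fractions and layer_densities must have equal length")
  }
  if (any(layer_fractions <= 0)) {
    stop_validation("layer_fractions must all be positive")
  }
  if (abs(sum(layer_fractions) - 1) > 1e-9) {
    stop_validation("layer_fractions must sum to 1 (got %.12f)",
                    sum(layer_fractions))
  }
  if (any(layer_densities < 0 | layer_densities > 1)) {
    stop_validation("layer_densities must lie in [0, 1]")
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    stop_validation("noise_sd must be a single number >= 0")
  }
  structure(
    list(layer_fractions = as.numeric(layer_fractions),
         layer_densities = as.numeric(layer_densities),
         noise_sd = noise_sd, name = as.character(name),
         smooth = as.integer(smooth)),
    class = "laminar_model")
}

#' @export
print.laminar_model <- function(x, ...) {
  cat(sprintf("<laminar_model '%s': %d layers, noise_sd = %g>\n",
              x$name, length(x$layer_fractions), x$noise_sd))
  invisible(x)
}

#' Noise-free expected profile of a laminar model
#'
#' Evaluates the layer-density step function of a model at `depth_bins`
#' equidistant normalized depths (bin midpoints), applying the model's
#' moving-average smoothing if configured.
#'
#' @param model A [laminar_model()].
#' @param depth_bins Number of equidistant depth samples (>= 2).
#' @return Numeric vector of length `depth_bins`.
#' @export
model_profile <- function(model, depth_bins = 100) {
  stopifnot(inherits(model, "laminar_model"), depth_bins >= 2)
  depth <- (seq_len(depth_bins) - 0.5) / depth_bins
  edges <- cumsum(model$layer_fractions)
  layer <- findInterval(depth, c(0, edges), rightmost.closed = TRUE,
                        all.inside = TRUE)
  prof <- model$layer_densities[layer]
  if (model$smooth > 0) {
    k <- model$smooth
    w <- 2L * k + 1L
    padded <- c(rep(prof[1], k), prof, rep(prof[depth_bins], k))
    prof <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))
    prof <- prof[(k + 1L):(k + depth_bins)]
  }
  prof
}

#' Render a synthetic ribbon of laminar GLI profiles
#'
#' Concatenates one segment of profiles per area model along a virtual
#' cortical ribbon. Profile i is its area's expected profile (see
#' [model_profile()]) plus i.i.d. Gaussian noise with the model's
#' `noise_sd`, clipped to \[0, 1\]. Ground-truth border positions are the
#' cumulative segment boundaries, recorded as metadata (never inferred).
#'
#' @param models A single [laminar_model()] or list of them, ordered along
#'   the ribbon.
#' @param segment_lengths Number of traverses (profiles) per area; same
#'   length as `models`.
#' @param depth_bins Number of normalized-depth samples per profile.
#' @param seed Optional RNG seed; identical seeds give bitwise-identical
#'   ribbons.
#' @return An object of class `synthetic_ribbon`: list with `profiles`
#'   (`n_traverses x depth_bins` matrix), `true_borders` (traverse indices:
#'   a border at b separates traverses 1..b from b+1..n), `area_labels`,
#'   and `depth` (bin midpoints).
#' @examples
#' a <- laminar_model(c(0.1, 0.3, 0.3, 0.1, 0.2),
#'                    c(0.60, 0.40, 0.30, 0.50, 0.45), 0.03, "A")
#' b <- laminar_model(c(0.1, 0.3, 0.3, 0.1, 0.2),
#'                    c(0.60, 0.55, 0.30, 0.35, 0.45), 0.03, "B")
#' rib <- render_ribbon(list(a, b), c(76, 86), seed = 7)
#' rib$true_borders  # 76
#' @export
render_ribbon <- function(models, segment_lengths, depth_bins = 100,
                          seed = NULL) {
  if (inherits(models, "laminar_model")) models <- list(models)
  if (!length(models) || !all(vapply(models, inherits, TRUE, "laminar_model"))) {
    stop_validation("models must be laminar_model objects")
  }
  if (length(models) != length(segment_lengths)) {
    stop_validation("models and segment_lengths must have equal length")
  }
  if (any(segment_lengths < 1)) stop_validation("segment_lengths must be >= 1")
  if (depth_bins < 10) stop_validation("depth_bins must be >= 10")
  n <- sum(segment_lengths)
  labels <- rep(vapply(models, `[[`, "", "name"), segment_lengths)
  expected <- lapply(models, model_profile, depth_bins = depth_bins)
  profiles <- with_seed(seed, {
    out <- matrix(0, n, depth_bins)
    row <- 1L
    for (i in seq_along(models)) {
      m <- models[[i]]
      len <- segment_lengths[i]
      block <- matrix(rep(expected[[i]], each = len), len, depth_bins)
      if (m$noise_sd > 0) {
        block <- block + matrix(rnorm(len * depth_bins, sd = m$noise_sd),
                                len, depth_bins)
      }
      out[row:(row + len - 1L), ] <- block
      row <- row + len
    }
    out
  })
  profiles <- pmin(pmax(profiles, 0), 1)
  borders <- head(cumsum(segment_lengths), -1L)
  structure(
    list(profiles = profiles, true_borders = as.integer(borders),
         area_labels = labels,
         depth = (seq_len(depth_bins) - 0.5) / depth_bins),
    class = "synthetic_ribbon")
}

#' @export
print.synthetic_ribbon <- function(x, ...) {
  cat(sprintf("<synthetic_ribbon: %d traverses x %d depth bins, borders at [%s]>\n",
              nrow(x$profiles), ncol(x$profiles),
              paste(x$true_borders, collapse = ", ")))
  invisible(x)
}

#' Render a binary cell-body image of a synthetic cortical ribbon
#'
#' Draws a binarized "stained section" whose local foreground (cell) pixel
#' fraction follows the laminar models along cortical depth, between an
#' outer contour (depth 0, the layer I/II analogue) and an inner contour
#' (depth 1, the layer VI/white-matter analogue). With `curvature = 0` the
#' ribbon is a flat rectangle; positive curvature bends it into an annular
#' sector of outer radius `1/curvature` pixels.
#'
#' @param models List of [laminar_model()], ordered along the ribbon.
#' @param segment_px Arc length in pixels of each area segment, measured
#'   along the outer contour; same length as `models`.
#' @param thickness_px Ribbon thickness in pixels (>= 64).
#' @param curvature Curvature of the outer contour in 1/pixels (>= 0).
#'   Values with `thickness_px >= 1/curvature` would self-intersect and
#'   raise an error.
#' @param seed Optional RNG seed.
#' @return List with `image` (0/1 integer matrix, row 1 = top), `outer` and
#'   `inner` contour polylines (data.frames with 0-based pixel columns
#'   `x`, `y`), `true_border_arcpos` (arc-length positions of the area
#'   borders along the outer contour, pixels), and `models`.
#' @export
render_gli_image <- function(models, segment_px, thickness_px = 320,
                             curvature = 0, seed = NULL) {
  if (inherits(models, "laminar_model")) models <- list(models)
  if (length(models) != length(segment_px)) {
    stop_validation("models and segment_px must have equal length")
  }
  if (thickness_px < 64) stop_validation("thickness_px must be >= 64")
  if (curvature < 0) stop_validation("curvature must be >= 0")
  total <- sum(segment_px)
  borders_arc <- head(cumsum(segment_px), -1L)
  dens_at <- function(model, depth) {
    # piecewise-constant density over depth in [0,1]
    edges <- cumsum(model$layer_fractions)
    layer <- findInterval(depth, c(0, edges), rightmost.closed = TRUE,
                          all.inside = TRUE)
    model$layer_densities[layer]
  }
  seg_of <- function(arc) {
    findInterval(arc, c(0, cumsum(segment_px)), rightmost.closed = TRUE,
                 all.inside = TRUE)
  }
  if (curvature == 0) {
    nr <- as.integer(thickness_px); nc <- as.integer(total)
    depth <- (seq_len(nr) - 0.5) / nr
    arc <- seq_len(nc) - 0.5
    seg <- seg_of(arc)
    dens <- matrix(0, nr, nc)
    for (j in seq_len(nc)) dens[, j] <- dens_at(models[[seg[j]]], depth)
    img <- with_seed(seed,
      matrix(rbinom(nr * nc, 1L, as.vector(dens)), nr, nc))
    outer <- data.frame(x = c(0, nc - 1), y = c(0, 0))
    inner <- data.frame(x = c(0, nc - 1), y = c(nr - 1, nr - 1))
  } else {
    r_out <- 1 / curvature
    r_in <- r_out - thickness_px
    if (r_in <= 0) {
      stop_validation("curvature %.4g with thickness %d self-intersects",
                      curvature, thickness_px)
    }
    theta_max <- total / r_out
    if (theta_max > pi) {
      stop_validation("arc angle exceeds pi; reduce curvature or length")
    }
    # canvas: annular sector with centre at (0, r_out); row 1 at top
    nc <- as.integer(ceiling(2 * r_out * sin(theta_max / 2)) +
                       ceiling(thickness_px * sin(theta_max)) + 2L)
    nr <- as.integer(ceiling(r_out - r_in * cos(theta_max)) + 2L)
    cx <- 0.5; cy <- r_out + 0.5  # centre of curvature (x right, y down)
    px <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
    py <- matrix(rep(seq_len(nr) - 0.5, nc), nr, nc)
    dx <- px - cx; dy <- cy - py
    r <- sqrt(dx^2 + dy^2)
    theta <- atan2(dx, dy)  # 0 at top, increasing clockwise (to the right)
    inside <- r <= r_out & r >= r_in & theta >= 0 & theta <= theta_max
    depth <- (r_out - r) / thickness_px
    arc <- theta * r_out
    seg <- seg_of(pmin(pmax(arc, 0), total))
    dens <- matrix(0, nr, nc)
    for (k in seq_along(models)) {
      sel <- inside & seg == k
      dens[sel] <- dens_at(models[[k]], depth[sel])
    }
    img <- with_seed(seed, {
      out <- matrix(0L, nr, nc)
      out[inside] <- rbinom(sum(inside), 1L, dens[inside])
      out
    })
    tt <- seq(0, theta_max, length.out = max(64L, ceiling(total)))
    outer <- data.frame(x = cx + r_out * sin(tt) - 0.5,
                        y = cy - r_out * cos(tt) - 0.5)
    inner <- data.frame(x = cx + r_in * sin(tt) - 0.5,
                        y = cy - r_in * cos(tt) - 0.5)
  }
  list(image = img, outer = outer, inner = inner,
       true_border_arcpos = as.numeric(borders_arc), models = models)
}

#' Construct a label volume
#'
#' @param grid 3D integer array of area labels (0 = background).
#' @param affine 4x4 voxel-to-world (mm) transform; voxel indices 0-based.
#' @param vocabulary Named integer vector mapping area names to labels.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, affine, vocabulary) {
  if (length(dim(grid)) != 3L) stop_validation("grid must be a 3D array")
  if (!all(dim(affine) == c(4L, 4L))) stop_validation("affine must be 4x4")
  if (abs(det(affine)) < 1e-12) stop_validation("affine must be invertible")
  vocabulary <- setNames(as.integer(vocabulary), names(vocabulary))
  labs <- unique(as.integer(grid))
  unknown <- setdiff(labs, c(0L, vocabulary))
  if (length(unknown)) {
    stop_validation("grid contains labels outside the vocabulary: %s",
                    paste(unknown, collapse = ", "))
  }
  structure(list(grid = grid, affine = affine, vocabulary = vocabulary),
            class = "label_volume")
}

#' Generate multi-subject label volumes with known spatial jitter
#'
#' Stands in for a sample of individually mapped brains already warped to a
#' common reference space: each synthetic subject is the canonical area
#' layout displaced by a random rigid translation of scale `jitter_mm`
#' (per-axis i.i.d. Gaussian, rounded to whole voxels). Labels shifted
#' outside the grid are clipped with a warning.
#'
#' @param shape Integer vector of 3 grid dimensions.
#' @param affine 4x4 voxel-to-world transform (mm).
#' @param area_masks Named list of disjoint logical 3D arrays (the canonical
#'   layout), one per area.
#' @param n_subjects Number of subjects (>= 1).
#' @param jitter_mm Standard deviation of the per-axis translation (mm).
#' @param seed Optional RNG seed.
#' @return List with `volumes` (list of [label_volume()]), `canonical`
#'   (the undisplaced [label_volume()]), `vocabulary`, and `jitter_mm`.
#' @export
make_subject_labelsets <- function(shape, affine, area_masks, n_subjects,
                                   jitter_mm = 2, seed = NULL) {
  stopifnot(length(shape) == 3L, n_subjects >= 1)
  if (is.null(names(area_masks)) || any(names(area_masks) == "")) {
    stop_validation("area_masks must be a named list")
  }
  overlap <- Reduce(`+`, lapply(area_masks, function(m) m * 1L))
  if (any(overlap > 1L)) stop_validation("area masks must be disjoint")
  vocab <- setNames(seq_along(area_masks), names(area_masks))
  canon <- array(0L, shape)
  for (i in seq_along(area_masks)) canon[area_masks[[i]]] <- vocab[i]
  vox_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  shifts <- with_seed(seed, {
    matrix(rnorm(3L * n_subjects, sd = jitter_mm), n_subjects, 3L)
  })
  shift_vox <- round(sweep(shifts, 2L, vox_mm, `/`))
  clipped <- FALSE
  volumes <- lapply(seq_len(n_subjects), function(s) {
    g <- shift_grid(canon, shift_vox[s, ])
    if (attr(g, "clipped")) clipped <<- TRUE
    attr(g, "clipped") <- NULL
    label_volume(g, affine, vocab)
  })
  if (clipped) warning("jitter moved labels outside the grid; clipped")
  list(volumes = volumes, canonical = label_volume(canon, affine, vocab),
       vocabulary = vocab, jitter_mm = jitter_mm)
}

# integer-voxel translation of a 3D label array, zero-filled; attr "clipped"
# reports whether any nonzero label fell off the grid
shift_grid <- function(grid, shift) {
  d <- dim(grid)
  out <- array(0L, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    s <- as.integer(shift[a])
    lo <- max(1L, 1L - s); hi <- min(d[a], d[a] - s)
    if (hi < lo) {
      attr(out, "clipped") <- any(grid != 0L)
      return(out)
    }
    src[[a]] <- lo:hi
    dst[[a]] <- src[[a]] + s
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- grid[src[[1]], src[[2]], src[[3]]]
  attr(out, "clipped") <- sum(out != 0L) < sum(grid != 0L)
  out
}

#' Canonical demo layout of cuboid areas
#'
#' Utility producing a named list of disjoint cuboid masks spread along the
#' x axis of a grid, used by the demo pipeline and tests.
#'
#' @param shape 3-vector of grid dimensions.
#' @param areas Area names.
#' @param size Cuboid edge length in voxels.
#' @return Named list of logical arrays.
#' @export
demo_area_layout <- function(shape, areas = c("A1", "A2", "A3"), size = 6L) {
  stopifnot(length(shape) == 3L, size >= 1)
  n <- length(areas)
  gap <- max(1L, (shape[1] - n * size) %/% (n + 1L))
  if (gap * (n + 1L) + n * size > shape[1] + size) {
    stop_validation("grid too small for %d areas of size %d", n, size)
  }
  y0 <- max(1L, (shape[2] - size) %/% 2L)
  z0 <- max(1L, (shape[3] - size) %/% 2L)
  out <- list()
  x <- gap
  for (a in areas) {
    m <- array(FALSE, shape)
    m[(x + 1L):min(shape[1], x + size),
      (y0 + 1L):min(shape[2], y0 + size),
      (z0 + 1L):min(shape[3], z0 + size)] <- TRUE
    out[[a]] <- m
    x <- x + size + gap
  }
  out
}

#' Synthetic areal volume table
#'
#' Emulates a volumetry study: `n_brains` brains, both hemispheres, two
#' genders, one whole-brain volume per brain and per-area fractions drawn
#' around area-specific baselines with Gaussian noise. Optionally one area
#' is inflated in the left hemisphere by `effect_sd` noise standard
#' deviations, providing a known ground-truth group difference.
#'
#' @param n_brains Number of brains (half per gender).
#' @param areas Area names.
#' @param base_range Range of baseline whole-brain fractions per area.
#' @param noise_sd Standard deviation of the fraction noise.
#' @param effect_area Optional area receiving a left-hemisphere inflation.
#' @param effect_sd Effect size in units of `noise_sd`.
#' @param whole_brain_mm3 Whole-brain volume (mm^3).
#' @param seed Optional RNG seed.
#' @return A [volume_table()].
#' @export
synth_volume_table <- function(n_brains = 10, areas = paste0("ar", 1:7),
                               base_range = c(0.001, 0.004),
                               noise_sd = 3e-4, effect_area = NULL,
                               effect_sd = 3, whole_brain_mm3 = 1.2e6,
                               seed = NULL) {
  stopifnot(n_brains >= 2)
  brains <- sprintf("b%02d", seq_len(n_brains))
  gender <- rep(c("f", "m"), length.out = n_brains)
  rows <- expand.grid(brain = brains, hemisphere = c("L", "R"), area = areas,
                      stringsAsFactors = FALSE)
  rows$gender <- gender[match(rows$brain, brains)]
  fractions <- with_seed(seed, {
    base <- setNames(runif(length(areas), base_range[1], base_range[2]),
                     areas)
    fr <- base[rows$area] + rnorm(nrow(rows), 0, noise_sd)
    if (!is.null(effect_area)) {
      sel <- rows$area == effect_area & rows$hemisphere == "L"
      fr[sel] <- fr[sel] + effect_sd * noise_sd
    }
    fr
  })
  fractions <- pmax(fractions, 1e-6)
  volume_table(rows$brain, rows$hemisphere, rows$gender, rows$area,
               fractions * whole_brain_mm3,
               rep(whole_brain_mm3, nrow(rows)))
}
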