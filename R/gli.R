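#' Compute a Grey Level Index image from a binarized cell image
#'
#' The GLI is the areal fraction of cell-body (foreground) pixels in a small
#' square window of the binarized histological image; with the default
#' non-overlapping 16 x 16 pixel window each output cell is the foreground
#' fraction of one window, so the mean GLI over the windowed region equals
#' its total foreground fraction exactly. Trailing partial windows are
#' dropped.
#'
#' @param image Binary matrix (0 = background, 1 = cell); logical accepted.
#' @param window_px Window side in pixels (>= 2).
#' @param stride Window step in pixels; defaults to `window_px`
#'   (non-overlapping).
#' @param resolution_um_per_px Source resolution in micrometres per pixel,
#'   carried as metadata (default 1.02).
#' @return Object of class `gli_image`: list with `values` (matrix of
#'   fractions in \[0,1\]), `window_px`, `stride`, `resolution_um_per_px`.
#' @examples
#' img <- matrix(rbinom(64 * 64, 1, 0.4), 64, 64)
#' g <- compute_gli(img, window_px = 16)
#' stopifnot(abs(mean(g$values) - mean(img)) < 1e-12)
#' @export
compute_gli <- function(image, window_px = 16, stride = window_px,
                        resolution_um_per_px = 1.02) {
  if (is.logical(image)) image <- image * 1L
  if (!is.matrix(image) || !all(image %in% c(0L, 1L))) {
    stop_validation("image must be a binary (0/1) matrix; binarize it first")
  }
  if (window_px < 2) stop_validation("window_px must be >= 2")
  if (stride < 1) stop_validation("stride must be >= 1")
  nr <- nrow(image); nc <- ncol(image)
  if (nr < window_px || nc < window_px) {
    stop_validation("image smaller than one %dx%d window", window_px, window_px)
  }
  # summed-area table for O(1) window sums
  sat <- rbind(0, cbind(0, apply(apply(image, 2L, cumsum), 1L, cumsum)))
  sat <- t(sat)  # careful: apply transposes; restore (nr+1) x (nc+1)
  r0 <- seq(1L, nr - window_px + 1L, by = stride)
  c0 <- seq(1L, nc - window_px + 1L, by = stride)
  vals <- outer(r0, c0, function(r, c) {
    (sat[cbind(r + window_px, c + window_px)] - sat[cbind(r, c + window_px)] -
       sat[cbind(r + window_px, c)] + sat[cbind(r, c)]) / (window_px^2)
  })
  structure(list(values = vals, window_px = as.integer(window_px),
                 stride = as.integer(stride),
                 resolution_um_per_px = resolution_um_per_px),
            class = "gli_image")
}

#' @export
print.gli_image <- function(x, ...) {
  cat(sprintf("<gli_image: %d x %d cells, window %d px, stride %d px>\n",
              nrow(x$values), ncol(x$values), x$window_px, x$stride))
  invisible(x)
}

# Convert a source-pixel polyline (0-based x,y) to GLI-grid coordinates
# (0-based col,row units of the windowed grid).
contour_to_grid <- function(contour, window_px, stride = window_px) {
  data.frame(x = (contour$x + 0.5 - window_px / 2) / stride,
             y = (contour$y + 0.5 - window_px / 2) / stride)
}

# Rasterize a polyline onto grid cells (1-based matrix indices).
rasterize_polyline <- function(contour, dims) {
  x <- contour$x; y <- contour$y
  pts <- lapply(seq_len(length(x) - 1L), function(i) {
    n <- max(2L, ceiling(2 * max(abs(x[i + 1] - x[i]), abs(y[i + 1] - y[i]))) + 1L)
    t <- seq(0, 1, length.out = n)
    cbind(x[i] + t * (x[i + 1] - x[i]), y[i] + t * (y[i + 1] - y[i]))
  })
  pts <- do.call(rbind, pts)
  ij <- cbind(pmin(pmax(round(pts[, 2]) + 1L, 1L), dims[1]),
              pmin(pmax(round(pts[, 1]) + 1L, 1L), dims[2]))
  m <- matrix(FALSE, dims[1], dims[2])
  m[unique(ij, MARGIN = 1L)] <- TRUE
  m
}

# Even-odd ray-casting point-in-polygon, vectorized over points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Ribbon mask between two cortical contours
#'
#' Fills the simply connected region bounded by the outer contour and the
#' reversed inner contour on a grid, including cells the contours pass
#' through.
#'
#' @param dims Grid dimensions (rows, cols).
#' @param outer,inner Polylines (data.frames `x`, `y` in 0-based grid
#'   coordinates).
#' @return Logical matrix.
#' @export
ribbon_mask <- function(dims, outer, inner) {
  vx <- c(outer$x, rev(inner$x)); vy <- c(outer$y, rev(inner$y))
  cc <- rep(seq_len(dims[2]) - 1, each = dims[1])
  rr <- rep(seq_len(dims[1]) - 1, dims[2])
  m <- matrix(points_in_polygon(cc, rr, vx, vy), dims[1], dims[2])
  m | rasterize_polyline(outer, dims) | rasterize_polyline(inner, dims)
}

#' Solve the laminar depth field over a cortical ribbon
#'
#' Solves the Laplace equation on the ribbon mask with Dirichlet boundary
#' values 0 on the outer contour (layer I/II analogue) and 1 on the inner
#' contour (layer VI/white-matter analogue), and natural no-flux conditions
#' on the remaining mask boundary (the cut edges of the ribbon). The
#' harmonic field defines the normalized cortical depth; its gradient
#' streamlines serve as non-crossing traverses. The system is solved
#' directly on the 5-point stencil; an error is raised if the residual
#' exceeds `tol`.
#'
#' @param mask Logical matrix: the ribbon.
#' @param outer,inner Either logical matrices marking Dirichlet cells, or
#'   polylines (data.frames `x`, `y`, 0-based grid coords) rasterized onto
#'   the mask.
#' @param tol Maximum admissible residual (infinity norm) of the discrete
#'   system.
#' @return Numeric matrix: depth in \[0,1\] inside the mask, NA outside.
#' @export
solve_depth_field <- function(mask, outer, inner, tol = 1e-8) {
  stopifnot(is.matrix(mask), is.logical(mask))
  dims <- dim(mask)
  as_dirichlet <- function(b) {
    if (is.matrix(b) && is.logical(b)) b else rasterize_polyline(b, dims)
  }
  d0 <- as_dirichlet(outer) & mask
  d1 <- as_dirichlet(inner) & mask
  if (!any(d0) || !any(d1)) {
    stop_validation("contours must intersect the mask")
  }
  d1 <- d1 & !d0
  fixed <- d0 | d1
  unknown <- mask & !fixed
  nu <- sum(unknown)
  if (nu == 0L) {
    f <- matrix(NA_real_, dims[1], dims[2])
    f[d0] <- 0; f[d1] <- 1
    return(f)
  }
  idx <- matrix(0L, dims[1], dims[2])
  idx[unknown] <- seq_len(nu)
  val <- matrix(0, dims[1], dims[2]); val[d1] <- 1
  which_u <- which(unknown, arr.ind = TRUE)
  ti <- tj <- integer(0); tx <- numeric(0)
  diag_cnt <- numeric(nu)
  rhs <- numeric(nu)
  for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    ni <- which_u[, 1] + off[1]; nj <- which_u[, 2] + off[2]
    inb <- ni >= 1L & ni <= dims[1] & nj >= 1L & nj <= dims[2]
    nidx <- rep(NA_integer_, nu)
    inmask <- rep(FALSE, nu)
    inmask[inb] <- mask[cbind(ni[inb], nj[inb])]
    diag_cnt <- diag_cnt + inmask
    nb_unknown <- inmask
    nb_unknown[inmask] <- unknown[cbind(ni[inmask], nj[inmask])]
    if (any(nb_unknown)) {
      ti <- c(ti, which(nb_unknown))
      tj <- c(tj, idx[cbind(ni[nb_unknown], nj[nb_unknown])])
      tx <- c(tx, rep(-1, sum(nb_unknown)))
    }
    nb_fixed <- inmask & !nb_unknown
    if (any(nb_fixed)) {
      rhs[nb_fixed] <- rhs[nb_fixed] + val[cbind(ni[nb_fixed], nj[nb_fixed])]
    }
  }
  A <- Matrix::sparseMatrix(i = c(ti, seq_len(nu)), j = c(tj, seq_len(nu)),
                            x = c(tx, diag_cnt), dims = c(nu, nu))
  sol <- as.numeric(Matrix::solve(A, rhs))
  res <- max(abs(A %*% sol - rhs))
  if (res > tol) {
    stop_validation("depth field solve did not converge (residual %.3e)", res)
  }
  f <- matrix(NA_real_, dims[1], dims[2])
  f[unknown] <- sol
  f[d0] <- 0; f[d1] <- 1
  f
}

# Bilinear interpolation tolerant of NA cells (weights renormalized over
# available neighbours). x, y are 0-based grid coordinates (col, row).
interp_field <- function(field, x, y) {
  nr <- nrow(field); nc <- ncol(field)
  x <- pmin(pmax(x, 0), nc - 1); y <- pmin(pmax(y, 0), nr - 1)
  j0 <- pmin(floor(x), nc - 2); i0 <- pmin(floor(y), nr - 2)
  fx <- x - j0; fy <- y - i0
  v <- matrix(c(field[cbind(i0 + 1, j0 + 1)], field[cbind(i0 + 1, j0 + 2)],
                field[cbind(i0 + 2, j0 + 1)], field[cbind(i0 + 2, j0 + 2)]),
              ncol = 4L)
  w <- cbind((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  w[is.na(v)] <- 0
  v[is.na(v)] <- 0
  s <- rowSums(w)
  out <- rowSums(v * w) / s
  out[s == 0] <- NA_real_
  out
}

# Numerical gradient of the interpolated field at 0-based points.
grad_field <- function(field, x, y, h = 0.5) {
  gx <- (interp_field(field, x + h, y) - interp_field(field, x - h, y)) / (2 * h)
  gy <- (interp_field(field, x, y + h) - interp_field(field, x, y - h)) / (2 * h)
  cbind(gx, gy)
}

# Equidistant arclength positions along a polyline; returns 0-based coords
# and arclength values.
polyline_seeds <- function(contour, n) {
  x <- contour$x; y <- contour$y
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- (seq_len(n) - 0.5) / n * total
  xi <- approx(s, x, xout = target)$y
  yi <- approx(s, y, xout = target)$y
  list(x = xi, y = yi, arclength = target, total = total)
}

#' Extract depth-normalized laminar profiles along a cortical ribbon
#'
#' Traverses are streamlines of the harmonic depth-field gradient, seeded at
#' equidistant arc-length positions on the outer contour and traced from the
#' outer (depth 0) to the inner (depth 1) contour; because the field is
#' harmonic the streamlines never cross. Each profile is the GLI sampled by
#' bilinear interpolation at `depth_bins` equidistant normalized depths.
#' Traverses whose streamline leaves the ribbon before completing are
#' excluded and reported.
#'
#' @param gli A [compute_gli()] result, or a plain matrix of GLI values.
#' @param outer,inner Contour polylines. With `contour_units = "pixels"`
#'   (the default for a `gli_image`) coordinates are 0-based source-image
#'   pixels and are converted to the GLI grid; with `"grid"` they are
#'   already 0-based GLI-grid coordinates.
#' @param n_traverses Number of traverses (>= 2).
#' @param depth_bins Number of equidistant normalized-depth samples.
#' @param contour_units `"pixels"` or `"grid"`.
#' @return Object of class `profile_set`: `profiles`
#'   (`n_traverses x depth_bins` matrix, excluded traverses removed),
#'   `traverse_arclength` (mm along the outer contour), `depth_bins`,
#'   `excluded` (indices of excluded traverses).
#' @export
extract_profiles <- function(gli, outer, inner, n_traverses,
                             depth_bins = 100, contour_units = NULL) {
  if (inherits(gli, "gli_image")) {
    values <- gli$values
    if (is.null(contour_units)) contour_units <- "pixels"
    if (contour_units == "pixels") {
      outer <- contour_to_grid(outer, gli$window_px, gli$stride)
      inner <- contour_to_grid(inner, gli$window_px, gli$stride)
    }
    mm_per_cell <- gli$stride * gli$resolution_um_per_px / 1000
  } else {
    values <- gli
    mm_per_cell <- 1
  }
  if (n_traverses < 2) stop_validation("n_traverses must be >= 2")
  dims <- dim(values)
  mask <- ribbon_mask(dims, outer, inner)
  field <- solve_depth_field(mask, outer, inner)
  seeds <- polyline_seeds(outer, n_traverses)
  depth_targets <- (seq_len(depth_bins) - 0.5) / depth_bins
  h <- 0.25
  max_steps <- as.integer(20 * sum(dims) / h)
  profiles <- matrix(NA_real_, n_traverses, depth_bins)
  # trace all streamlines in lockstep (midpoint steps along the normalized
  # gradient); paths are recorded per step for depth resampling
  x <- seeds$x; y <- seeds$y
  f <- interp_field(field, x, y)
  active <- !is.na(f) & f < depth_targets[depth_bins]
  failed <- is.na(f)
  path_x <- list(x); path_y <- list(y); path_f <- list(f)
  for (step in seq_len(max_steps)) {
    if (!any(active)) break
    xa <- x[active]; ya <- y[active]
    g <- grad_field(field, xa, ya)
    gn <- sqrt(rowSums(g^2))
    bad <- !is.finite(gn) | gn < 1e-12
    xm <- xa + 0.5 * h * g[, 1] / gn; ym <- ya + 0.5 * h * g[, 2] / gn
    gm <- grad_field(field, xm, ym)
    gmn <- sqrt(rowSums(gm^2))
    use1 <- !is.finite(gmn) | gmn < 1e-12
    gm[use1, ] <- g[use1, ]; gmn[use1] <- gn[use1]
    xn <- xa + h * gm[, 1] / gmn; yn <- ya + h * gm[, 2] / gmn
    fn <- interp_field(field, xn, yn)
    bad <- bad | is.na(fn)
    idx <- which(active)
    x[idx[!bad]] <- xn[!bad]; y[idx[!bad]] <- yn[!bad]
    f[idx[!bad]] <- fn[!bad]
    failed[idx[bad]] <- TRUE
    active[idx[bad]] <- FALSE
    active[idx[!bad]] <- fn[!bad] < depth_targets[depth_bins]
    path_x <- c(path_x, list(x)); path_y <- c(path_y, list(y))
    path_f <- c(path_f, list(f))
  }
  px <- do.call(rbind, path_x); py <- do.call(rbind, path_y)
  pfv <- do.call(rbind, path_f)
  excluded <- integer(0)
  for (k in seq_len(n_traverses)) {
    if (failed[k] || max(pfv[, k], na.rm = TRUE) < depth_targets[depth_bins]) {
      excluded <- c(excluded, k)
      next
    }
    ordf <- cummax(ifelse(is.na(pfv[, k]), 0, pfv[, k]))
    sx <- approx(ordf, px[, k], xout = depth_targets, ties = "ordered", rule = 2)$y
    sy <- approx(ordf, py[, k], xout = depth_targets, ties = "ordered", rule = 2)$y
    profiles[k, ] <- interp_field(values, sx, sy)
  }
  if (length(excluded)) {
    message(sprintf("extract_profiles: %d traverse(s) excluded (left ribbon): %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  keep <- setdiff(seq_len(n_traverses), excluded)
  if (anyNA(profiles[keep, , drop = FALSE])) {
    bad <- keep[apply(is.na(profiles[keep, , drop = FALSE]), 1L, any)]
    excluded <- sort(c(excluded, bad))
    keep <- setdiff(seq_len(n_traverses), excluded)
  }
  structure(
    list(profiles = profiles[keep, , drop = FALSE],
         traverse_arclength = seeds$arclength[keep] * mm_per_cell,
         depth_bins = as.integer(depth_bins),
         excluded = as.integer(excluded),
         endpoints = data.frame(x = x[keep], y = y[keep])),
    class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set: %d traverses x %d depth bins (%d excluded)>\n",
              nrow(x$profiles), x$depth_bins, length(x$excluded)))
  invisible(x)
}

#' @rdname extract_profiles
#' @param x A `profile_set` or matrix.
#' @export
as_profile_matrix <- function(x) {
  if (inherits(x, "profile_set")) x$profiles
  else if (inherits(x, "synthetic_ribbon")) x$profiles
  else if (is.matrix(x)) x
  else stop_validation("cannot interpret object as profiles")
}
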