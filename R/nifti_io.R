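# NIfTI-1 I/O. Affines map 0-based voxel indices to world mm (RAS); they are
# stored in the sform (code 2) only, which RNifti round-trips exactly.

nifti_affine <- function(img) {
  m <- RNifti::xform(img)
  attributes(m) <- list(dim = dim(m))
  m
}

as_nifti_with_affine <- function(grid, affine) {
  img <- RNifti::asNifti(grid)
  img <- RNifti::`qform<-`(img, structure(diag(4), code = 0L))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img
}

check_3d <- function(img, path) {
  d <- dim(img)
  if (length(d) != 3L) {
    stop_validation("%s: expected a 3D volume, got %d dimensions", path,
                    length(d))
  }
  hdr <- RNifti::niftiHeader(img)
  if (hdr$sform_code == 0 && hdr$qform_code == 0) {
    stop_validation("%s: no usable affine (qform and sform both absent)", path)
  }
}

#' Read and write label volumes as NIfTI
#'
#' Label volumes are stored as int16 with the voxel-to-world affine in the
#' sform; `.nii` and `.nii.gz` are both accepted. On read, labels are
#' checked against the declared vocabulary and an unknown label is an error
#' naming an offending voxel.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param vocabulary Named integer vector of admissible labels.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, vocabulary) {
  img <- RNifti::readNifti(path)
  check_3d(img, path)
  grid <- array(as.integer(as.array(img)), dim(img))
  unknown <- !(grid %in% c(0L, as.integer(vocabulary)))
  if (any(unknown)) {
    v <- arrayInd(which(unknown)[1], dim(grid)) - 1L
    stop_validation("%s: label %d at voxel (%d, %d, %d) not in vocabulary",
                    path, grid[which(unknown)[1]], v[1], v[2], v[3])
  }
  label_volume(grid, nifti_affine(img), vocabulary)
}

#' @rdname read_label_volume
#' @param volume A [label_volume()].
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  img <- as_nifti_with_affine(volume$grid, volume$affine)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read and write probability maps as NIfTI
#'
#' Probability maps are stored as float32 (probabilities are quantized to
#' single precision, about 1e-7 relative); the affine is preserved exactly.
#'
#' @param path File path.
#' @param area Area name to attach on read.
#' @param n_subjects Subject count to attach on read.
#' @return A `probability_map`.
#' @export
read_pmap <- function(path, area = NA_character_, n_subjects = NA_integer_) {
  img <- RNifti::readNifti(path)
  check_3d(img, path)
  grid <- array(as.numeric(as.array(img)), dim(img))
  if (min(grid) < 0 || max(grid) > 1 + 1e-6) {
    stop_validation("%s: values outside [0, 1]; not a probability map", path)
  }
  structure(list(grid = grid, affine = nifti_affine(img), area = area,
                 n_subjects = n_subjects),
            class = "probability_map")
}

#' @rdname read_pmap
#' @param pmap A `probability_map`.
#' @export
write_pmap <- function(pmap, path) {
  stopifnot(inherits(pmap, "probability_map"))
  img <- as_nifti_with_affine(pmap$grid, pmap$affine)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname read_label_volume
#' @param mpm An `mpm_volume`.
#' @export
write_mpm <- function(mpm, path) {
  stopifnot(inherits(mpm, "mpm_volume"))
  img <- as_nifti_with_affine(mpm$grid, mpm$affine)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Write a binary cell image as PNG
#'
#' @param image 0/1 matrix (row 1 = top of the image).
#' @param path Output path.
#' @export
write_cell_image <- function(image, path) {
  png::writePNG(matrix(as.numeric(image), nrow(image), ncol(image)), path)
  invisible(path)
}

#' Read a binary cell image from PNG/TIFF
#'
#' Accepts single-channel or RGB(A) images; pixels with intensity > 0.5 are
#' foreground.
#'
#' @param path Input path (`.png`, `.tif`, `.tiff`).
#' @return 0/1 integer matrix.
#' @export
read_cell_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop_validation("the 'tiff' package is required to read %s", path)
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  matrix(as.integer(arr > 0.5), nrow(arr), ncol(arr))
}

#' Write/read a profile set as CSV plus JSON metadata
#'
#' The CSV holds one profile per row; the JSON sidecar
#' (`<path>.json`) records arc-length positions, depth bin count and
#' excluded traverses.
#'
#' @param profile_set A `profile_set`.
#' @param path CSV path.
#' @export
write_profile_set <- function(profile_set, path) {
  stopifnot(inherits(profile_set, "profile_set"))
  write.csv(as.data.frame(profile_set$profiles), path, row.names = FALSE)
  meta <- list(traverse_arclength = profile_set$traverse_arclength,
               depth_bins = profile_set$depth_bins,
               excluded = profile_set$excluded)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_profile_set
#' @export
read_profile_set <- function(path) {
  profiles <- as.matrix(read.csv(path))
  dimnames(profiles) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(profiles = profiles,
                 traverse_arclength = meta$traverse_arclength,
                 depth_bins = as.integer(meta$depth_bins),
                 excluded = as.integer(meta$excluded)),
            class = "profile_set")
}
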