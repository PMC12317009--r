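#' Default laminar models of the demo pipeline
#'
#' Two five-layer models emulating neighbouring premotor-like areas: both
#' share an overall density envelope, but differ by 0.15 GLI in layers II
#' and IV (one has a pronounced layer IV - "dysgranular-like" - the other a
#' denser layer II and weak layer IV - "agranular-like"), which is the kind
#' of laminar contrast the border statistic is built to detect.
#'
#' @param noise_sd GLI noise standard deviation applied to both models.
#' @param smooth Profile smoothing half-width in depth bins.
#' @return Named list of two [laminar_model()] objects.
#' @export
default_laminar_models <- function(noise_sd = 0.03, smooth = 0) {
  list(
    agranular = laminar_model(c(0.10, 0.30, 0.30, 0.10, 0.20),
                              c(0.60, 0.40, 0.30, 0.50, 0.45),
                              noise_sd, "agranular", smooth),
    dysgranular = laminar_model(c(0.10, 0.30, 0.30, 0.10, 0.20),
                                c(0.60, 0.55, 0.30, 0.35, 0.45),
                                noise_sd, "dysgranular", smooth))
}

#' Default pipeline configuration
#'
#' All statistical defaults equal the mapping protocol's stated parameters:
#' GLI window 16 px at 1.02 um/px, blocks of 12-24 profiles, alpha 0.001
#' (Hotelling T-squared, Bonferroni corrected), MPM threshold 0.4,
#' coordinate-assignment threshold 0.2, 10 subjects, permutation count
#' 10000.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @return Nested named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    synth = list(noise_sd = 0.03, segment_lengths = c(76L, 86L),
                 depth_bins = 100L, n_subjects = 10L, jitter_mm = 2,
                 shape = c(48L, 24L, 24L), vox_mm = 1,
                 areas = c("A1", "A2", "A3"), area_size = 6L),
    borders = list(block_min = 12L, block_max = 24L, alpha = 0.001,
                   min_support = NULL, merge_window = 5L, shrinkage = 0),
    atlas = list(mpm_threshold = 0.4, connectivity = 26L,
                 assign_threshold = 0.2),
    gli = list(window_px = 16L, stride = 16L, resolution_um_per_px = 1.02),
    volumes = list(n_perm = 10000L, method = "BH", q = 0.05)
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config A config as produced by [default_config()] (possibly
#'   modified).
#' @return The config, invisibly, or an error describing the first invalid
#'   field.
#' @export
validate_config <- function(config) {
  chk <- function(ok, msg, ...) if (!ok) stop_validation(msg, ...)
  chk(is.list(config), "config must be a list")
  chk(is_scalar_number(config$seed), "seed must be a number")
  b <- config$borders
  chk(b$alpha > 0 && b$alpha < 1, "borders$alpha must be in (0, 1)")
  chk(b$block_min >= 2 && b$block_max >= b$block_min,
      "borders block range invalid")
  a <- config$atlas
  chk(a$mpm_threshold >= 0 && a$mpm_threshold <= 1,
      "atlas$mpm_threshold must be in [0, 1]")
  chk(a$assign_threshold >= 0 && a$assign_threshold <= 1,
      "atlas$assign_threshold must be in [0, 1]")
  chk(a$connectivity %in% c(6, 18, 26), "atlas$connectivity must be 6/18/26")
  s <- config$synth
  chk(s$noise_sd >= 0, "synth$noise_sd must be >= 0")
  chk(all(s$segment_lengths >= 1), "synth$segment_lengths must be >= 1")
  chk(s$n_subjects >= 1, "synth$n_subjects must be >= 1")
  chk(config$gli$window_px >= 2, "gli$window_px must be >= 2")
  chk(config$volumes$n_perm >= 1000, "volumes$n_perm must be >= 1000")
  invisible(config)
}

#' Run the demo pipeline end to end
#'
#' Executes the 2D track (synthetic laminar ribbon -> feature vectors ->
#' sliding-window Mahalanobis border detection) and the 3D track (synthetic
#' multi-subject label volumes -> probability maps -> maximum probability
#' map, centres of gravity and pairwise map correlations) under a single
#' master seed, and returns a JSON-serializable run report. Identical
#' config and seed reproduce identical reports.
#'
#' @param config A [default_config()]-style configuration.
#' @param outdir Optional directory; if given, the report is written to
#'   `report.json` and the MPM/pmaps as NIfTI files there.
#' @return The report (nested list).
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  validate_config(config)
  s <- config$synth
  models <- default_laminar_models(noise_sd = s$noise_sd)
  ribbon <- render_ribbon(models, s$segment_lengths,
                          depth_bins = s$depth_bins,
                          seed = derive_seed(config$seed, "synth"))
  bs <- detect_borders(ribbon,
                       block_range = c(config$borders$block_min,
                                       config$borders$block_max),
                       alpha = config$borders$alpha,
                       min_support = config$borders$min_support,
                       merge_window = config$borders$merge_window,
                       shrinkage = config$borders$shrinkage)
  affine <- diag(c(rep(s$vox_mm, 3), 1))
  layout <- demo_area_layout(s$shape, s$areas, s$area_size)
  subjects <- make_subject_labelsets(s$shape, affine, layout,
                                     n_subjects = s$n_subjects,
                                     jitter_mm = s$jitter_mm,
                                     seed = derive_seed(config$seed, "atlas"))
  pmaps <- lapply(s$areas, function(a) build_pmap(subjects$volumes, a))
  names(pmaps) <- s$areas
  mpm <- build_mpm(pmaps, unmapped_threshold = config$atlas$mpm_threshold,
                   connectivity = config$atlas$connectivity)
  cog <- lapply(pmaps, function(p) round(unname(centre_of_gravity(p)), 6))
  pairs <- utils::combn(s$areas, 2L)
  corr <- apply(pairs, 2L, function(ab) {
    round(correlate_maps(pmaps[[ab[1]]], pmaps[[ab[2]]]), 6)
  })
  report <- list(
    package = "cytoarch",
    version = as.character(utils::packageVersion("cytoarch")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    borders = list(
      true = ribbon$true_borders,
      detected = bs$borders,
      support = bs$support,
      block_sizes = bs$block_sizes),
    atlas = list(
      n_subjects = s$n_subjects,
      centre_of_gravity = cog,
      mpm_assigned_voxels = sum(mpm$grid > 0),
      mpm_ties = mpm$n_ties,
      mpm_volumes_mm3 = as.list(label_volumes_mm3(mpm)),
      pair_correlations = setNames(as.list(round(corr, 6)),
                                   apply(pairs, 2L, paste, collapse = ":"))))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (a in s$areas) {
      write_pmap(pmaps[[a]], file.path(outdir, paste0("pmap_", a, ".nii.gz")))
    }
    write_mpm(mpm, file.path(outdir, "mpm.nii.gz"))
  }
  report
}
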