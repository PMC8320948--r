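#' Run the full segmentation and modelling pipeline
#'
#' Wires the stages end to end: read (or generate) a stack, detect and
#' correct inter-slice displacement artefacts, segment the nucleus
#' volume, optionally evaluate against ground truth, fit the spheroid
#' model and compute the surface map and its metrics. All artifacts are
#' written under `config$output`: nucleus and envelope masks as TIFF, the
#' per-slice metrics and surface metrics as CSV, the surface map as CSV,
#' and a JSON manifest echoing every parameter. Deterministic for a
#' fixed configuration.
#'
#' @param config configuration list, or the path of a YAML file holding
#'   one. Recognized entries: `input` (stack directory/file; omit to
#'   generate a phantom from `phantom`, a list of [phantom_params()]
#'   arguments), `output` (directory, required), `params` (list of
#'   [seg_params()] arguments), `voxel_size`, `align` (logical, default
#'   `TRUE`), `align_threshold`, `central_slice`, `gt` (ground-truth mask
#'   directory/file for evaluation), `eval_range` (inclusive slice
#'   range), `n_lon`, `n_lat` (surface grid), `seed`.
#' @return Invisibly, a list with the `NucleusVolume`, the `Spheroid`,
#'   the `SurfaceMap`, the surface metrics row, the evaluation (or
#'   `NULL`) and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$output))

  seg_p <- do.call(seg_params, config$params %||% list())  # fail early
  voxel_size <- config$voxel_size %||% DEFAULT_VOXEL_SIZE
  out <- config$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  t0 <- Sys.time()
  if (!is.null(config$input)) {
    stack <- read_stack(config$input, voxel_size)
    gt <- if (!is.null(config$gt)) read_mask(config$gt)
  } else {
    ph_args <- config$phantom %||% list()
    if (!is.null(config$seed)) ph_args$seed <- config$seed
    phantom <- generate_phantom(do.call(phantom_params, ph_args))
    stack <- phantom$stack
    voxel_size <- stack$voxel_size
    gt <- phantom$nucleus
  }

  shifts <- NULL
  if (isTRUE(config$align %||% TRUE) && n_slices(stack) >= 2L) {
    shifts <- detect_discontinuity(stack, config$align_threshold %||% 5)
    for (i in seq_len(nrow(shifts)))
      stack <- correct_shift(stack, shifts[i, ])
  }

  nucleus <- segment_volume(stack, seg_p,
                            central_slice = config$central_slice)
  write_mask(nucleus$mask, file.path(out, "nucleus"))
  write_mask(nucleus$envelope, file.path(out, "envelope"))
  utils::write.csv(nucleus$log, file.path(out, "slice_log.csv"),
                   row.names = FALSE)

  evaluation <- NULL
  if (!is.null(gt)) {
    evaluation <- evaluate_volume(nucleus, gt,
                                  slice_range = config$eval_range)
    utils::write.csv(evaluation$per_slice,
                     file.path(out, "evaluation.csv"), row.names = FALSE)
  }

  spheroid <- fit_spheroid(nucleus, voxel_size)
  map <- ray_distances(nucleus, spheroid,
                       n_lon = config$n_lon %||% 360L,
                       n_lat = config$n_lat %||% 180L,
                       voxel_size = voxel_size)
  metrics <- surface_metrics(map, nucleus, spheroid, voxel_size)
  utils::write.csv(metrics, file.path(out, "surface_metrics.csv"),
                   row.names = FALSE)
  utils::write.table(map$grid, file.path(out, "surface_map.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)

  manifest <- list(
    config = config,
    seg_params = unclass(seg_p),
    voxel_size = voxel_size,
    stack_dim = dim(stack),
    shifts = if (!is.null(shifts) && nrow(shifts)) shifts,
    central_slice = nucleus$central_slice,
    nucleus_voxels = sum(nucleus$mask),
    mean_jaccard = if (!is.null(evaluation)) evaluation$mean_jaccard,
    mean_hausdorff = if (!is.null(evaluation)) evaluation$mean_hausdorff,
    surface_metrics = as.list(metrics),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    package_version = as.character(utils::packageVersion("nesegment"))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(nucleus = nucleus, spheroid = spheroid, map = map,
                 metrics = metrics, evaluation = evaluation,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
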