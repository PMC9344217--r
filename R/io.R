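#' Write / read an OCT volume as a raw binary stack with a JSON sidecar
#'
#' Volumes are stored as little-endian float32 values in B-scan-major order
#' (`<prefix>.bin`) with a JSON sidecar (`<prefix>.json`) carrying dimensions,
#' pixel scales, identifiers and, when available, the ground-truth boundary
#' surfaces. The pair round-trips losslessly at float32 precision.
#'
#' @param volume An `oct_volume`.
#' @param prefix Output path prefix (without extension).
#' @param truth Include the attached `scene_truth` surfaces in the sidecar?
#' @return `write_volume()` returns `prefix` invisibly; `read_volume()`
#'   returns an `oct_volume` (with a `"truth_surfaces"` attribute when the
#'   sidecar holds truth).
#' @export
write_volume <- function(volume, prefix, truth = TRUE) {
  stopifnot(inherits(volume, "oct_volume"))
  H <- nrow(volume$frames[[1]]); W <- ncol(volume$frames[[1]])
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  for (f in volume$frames)
    writeBin(as.numeric(f), con, size = 4, endian = "little")
  tr <- attr(volume, "truth")
  sidecar <- list(
    n_slices = length(volume$frames), height = H, width = W,
    lateral_scale_mm = volume$lateral_scale,
    slice_scale_mm = volume$slice_scale,
    axial_scale_um = volume$axial_scale,
    person_id = volume$person_id, eye_id = volume$eye_id,
    laterality = volume$laterality)
  if (truth && !is.null(tr)) {
    sidecar$truth <- list(
      ilm = as.vector(tr$ilm), rpe = as.vector(tr$rpe),
      a_fovea_true = tr$a_fovea_true, a_macula_true = tr$a_macula_true,
      pit_center = unname(tr$pit_center), cprt_true_px = tr$cprt_true_px,
      noise_sigma = tr$noise_sigma)
  }
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_volume
#' @export
read_volume <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- meta$n_slices; H <- meta$height; W <- meta$width
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n * H * W, size = 4, endian = "little")
  frames <- lapply(seq_len(n), function(s)
    matrix(vals[((s - 1) * H * W + 1):(s * H * W)], H, W))
  vol <- structure(list(
    frames = frames, lateral_scale = meta$lateral_scale_mm,
    slice_scale = meta$slice_scale_mm, axial_scale = meta$axial_scale_um,
    person_id = meta$person_id, eye_id = meta$eye_id,
    laterality = meta$laterality), class = "oct_volume")
  if (!is.null(meta$truth)) {
    attr(vol, "truth_surfaces") <- list(
      ilm = matrix(meta$truth$ilm, n, W), rpe = matrix(meta$truth$rpe, n, W),
      a_fovea_true = meta$truth$a_fovea_true,
      a_macula_true = meta$truth$a_macula_true,
      pit_center = meta$truth$pit_center,
      cprt_true_px = meta$truth$cprt_true_px,
      noise_sigma = meta$truth$noise_sigma)
  }
  vol
}

#' Write / read boundary traces as CSV
#'
#' Long format: one row per (slice, column) with sub-pixel ILM and RPE rows
#' and validity flags.
#'
#' @param seg An `oct_volume_segmentation`.
#' @param path CSV path.
#' @return `write_traces()` the path, invisibly; `read_traces()` an
#'   `oct_volume_segmentation`.
#' @export
write_traces <- function(seg, path) {
  stopifnot(inherits(seg, "oct_volume_segmentation"))
  n_s <- nrow(seg$ilm); W <- ncol(seg$ilm)
  d <- tibble::tibble(
    slice = rep(seq_len(n_s), each = W),
    column = rep(seq_len(W), n_s),
    ilm_row = as.vector(t(seg$ilm)),
    rpe_row = as.vector(t(seg$rpe)),
    qc = rep(seg$qc, each = W))
  d$ilm_valid <- is.finite(d$ilm_row)
  d$rpe_valid <- is.finite(d$rpe_row)
  readr::write_csv(d, path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  n_s <- max(d$slice); W <- max(d$column)
  structure(list(
    ilm = matrix(d$ilm_row, n_s, W, byrow = TRUE),
    rpe = matrix(d$rpe_row, n_s, W, byrow = TRUE),
    qc = d$qc[match(seq_len(n_s), d$slice)],
    masks = NULL), class = "oct_volume_segmentation")
}

#' Pipeline configuration
#'
#' Collects generator, segmentation, morphometry and analysis settings with
#' their defaults, and round-trips losslessly through YAML. Defaults marked
#' `paper` come from the emulated study protocol; `assumption` defaults are
#' documented package choices.
#'
#' @param ... Overrides for any top-level entry.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_volumes = 3L,
    n_persons = 500L,
    generator = list( # scene_truth() arguments
      noise_sigma = 0.2, height = 650L, axial_scale_um = 2.6),
    segmentation = list(lambda = 0.1, max_jump = 15L, smooth_sigma = 1,
                        grad_tol = 1e-4),
    morphometry = list(window = 12L, central_slices = 32L),
    analysis = list(models = c(1L, 2L, 3L), sensitivity = TRUE, trend = TRUE),
    seed = 1L)
  cfg <- modifyList(cfg, list(...))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop_qc(paste0("config file not found: ", path), "foveapit_validation_error")
  structure(yaml::read_yaml(path), class = "pipeline_config")
}
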