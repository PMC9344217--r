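#' Locate the fovea center as the thinnest-retina point of a volume
#'
#' Builds the slice-by-column retinal thickness map (RPE minus ILM row), box-
#' smooths it over 3 slices x 11 columns (anisotropic because the slice pitch
#' is about four times the column pitch), and returns the rounded centroid of
#' the minimal connected region. Ties broken by lowest slice, then lowest
#' column.
#'
#' @param seg An `oct_volume_segmentation` (from [segment_volume()]), or a
#'   matrix of ILM rows if `rpe` is given separately.
#' @param rpe Optional matrix of RPE rows (same shape as `seg`).
#' @param smooth_slices,smooth_columns Box-filter extents (odd integers).
#' @param edge_margin Minimum distance of the center column from the lateral
#'   edges (the quadratic fit window); closer centers are a QC failure.
#' @return A list of class `fovea_center` with integer `slice` and `column`.
#' @section Errors: A minimum on the volume border, a center column within
#'   `edge_margin` of the lateral edges, or fewer than 90% finite thickness
#'   cells raise a `foveapit_qc_error` (pit not captured by the scan).
#' @export
locate_fovea_center <- function(seg, rpe = NULL,
                                smooth_slices = 3L, smooth_columns = 11L,
                                edge_margin = 12L) {
  if (inherits(seg, "oct_volume_segmentation")) {
    ilm <- seg$ilm; rpe <- seg$rpe
  } else ilm <- seg
  stopifnot(is.matrix(ilm), is.matrix(rpe), identical(dim(ilm), dim(rpe)))
  thick <- rpe - ilm
  if (mean(is.finite(thick)) < 0.9)
    stop_qc("fewer than 90% of thickness cells are valid.", "foveapit_qc_error")
  sm <- box_smooth2(thick, smooth_slices, smooth_columns)

  mn <- min(sm, na.rm = TRUE)
  tol <- 1e-9 * (1 + abs(mn))
  minimal <- is.finite(sm) & sm <= mn + tol
  seedcell <- which(minimal)[1] # column-major: lowest column, then slice
  comp <- flood_component(minimal, seedcell)
  idx <- which(comp, arr.ind = TRUE)
  slice <- as.integer(floor(mean(idx[, 1]) + 0.5))
  column <- as.integer(floor(mean(idx[, 2]) + 0.5))

  n_s <- nrow(sm); n_c <- ncol(sm)
  if (slice <= 1L || slice >= n_s)
    stop_qc("thickness minimum on the volume border: pit not captured.",
            "foveapit_qc_error")
  if (column <= edge_margin || column > n_c - edge_margin)
    stop_qc("fovea center too close to the lateral edge for curve fitting.",
            "foveapit_qc_error")
  structure(list(slice = slice, column = column), class = "fovea_center")
}

# Box filter with edge-truncated normalization (NA-aware).
box_smooth2 <- function(m, k_rows, k_cols) {
  stopifnot(k_rows %% 2 == 1, k_cols %% 2 == 1)
  vals <- m; vals[!is.finite(vals)] <- 0
  wts <- matrix(as.numeric(is.finite(m)), nrow(m), ncol(m))
  shift_sum <- function(x, k, along) {
    r <- (k - 1L) %/% 2L
    out <- 0
    n <- if (along == 1) nrow(x) else ncol(x)
    for (off in (-r):r) {
      idx <- seq_len(n) + off
      keep <- idx >= 1L & idx <= n
      pad <- matrix(0, nrow(x), ncol(x))
      if (along == 1) pad[keep, ] <- x[idx[keep], , drop = FALSE]
      else pad[, keep] <- x[, idx[keep], drop = FALSE]
      out <- out + pad
    }
    out
  }
  num <- shift_sum(shift_sum(vals, k_rows, 1), k_cols, 2)
  den <- shift_sum(shift_sum(wts, k_rows, 1), k_cols, 2)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# 4-connected component of `mask` containing linear index `start`.
flood_component <- function(mask, start) {
  comp <- matrix(FALSE, nrow(mask), ncol(mask))
  queue <- start
  comp[start] <- TRUE
  nr <- nrow(mask)
  while (length(queue)) {
    cur <- queue[length(queue)]; queue <- queue[-length(queue)]
    r <- (cur - 1L) %% nr + 1L; cl <- (cur - 1L) %/% nr + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1]; cc <- cl + d[2]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= ncol(mask)) {
        id <- (cc - 1L) * nr + rr
        if (mask[id] && !comp[id]) { comp[id] <- TRUE; queue <- c(queue, id) }
      }
    }
  }
  comp
}

#' Center point retinal thickness
#'
#' The ILM-to-RPE distance at the fovea center column, in pixels and in
#' micrometers (`cprt_px * axial_scale`).
#'
#' @param ilm,rpe Boundary row values: numeric vectors over columns for the
#'   center slice (or single values at the center column).
#' @param center A [locate_fovea_center()] result, or an integer column.
#' @param axial_scale Micrometers per row.
#' @return A list with `cprt_px` and `cprt_um`.
#' @section Errors: Non-positive thickness raises a `foveapit_qc_error`.
#' @export
compute_cprt <- function(ilm, rpe, center, axial_scale = 2.6) {
  col <- if (inherits(center, "fovea_center")) center$column else as.integer(center)
  i <- if (length(ilm) == 1L) ilm else ilm[col]
  r <- if (length(rpe) == 1L) rpe else rpe[col]
  if (!is.finite(i) || !is.finite(r))
    stop_qc("boundary traces invalid at the center column.", "foveapit_qc_error")
  px <- r - i
  if (px <= 0)
    stop_qc("non-positive retinal thickness at the fovea center.",
            "foveapit_qc_error")
  list(cprt_px = px, cprt_um = px * axial_scale)
}

#' Foveal curvature from a quadratic fit of the ILM around the center
#'
#' Ordinary least-squares quadratic of ILM row against column over the window
#' of 12 pixels left and right of the fovea center (25 points, fitted in
#' pixel coordinates). Rows increase downward, so a pit makes the raw leading
#' coefficient negative; the returned curvature is sign-adjusted so a normal
#' pit is positive ("steeper" = larger).
#'
#' @param ilm Numeric vector of ILM rows for the center B-scan (may contain
#'   `NA` for invalid columns).
#' @param center_column Fovea center column.
#' @param window Half-width of the fit window in columns (12 per protocol).
#' @return Foveal curvature `fc` (rows/column^2); multiply by 100 for the
#'   conventional reporting scale.
#' @section Errors: A window clipped by the image edge, or any invalid column
#'   inside it, raises a `foveapit_qc_error`.
#' @export
fit_foveal_curvature <- function(ilm, center_column, window = 12L) {
  lo <- center_column - window; hi <- center_column + window
  if (lo < 1L || hi > length(ilm))
    stop_qc("fit window clipped by the image edge.", "foveapit_qc_error")
  y <- ilm[lo:hi]
  if (any(!is.finite(y)))
    stop_qc("invalid ILM columns inside the fit window.", "foveapit_qc_error")
  x <- seq(-window, window)
  -unname(coef(lm(y ~ x + I(x^2)))[3])
}

#' Macular curvature from per-B-scan quadratic fits of the RPE
#'
#' For each of the 32 central B-scans, fits a quadratic to the RPE boundary
#' over all valid columns (pixel coordinates) and takes the sign-adjusted
#' leading coefficient; the macular curvature is the median of the per-scan
#' values. Slices with fewer than 90% valid columns are dropped; more than 3
#' unusable slices is a QC failure.
#'
#' @param rpe Matrix of RPE rows (`n_slices x width`), e.g.
#'   `segment_volume(vol)$rpe`.
#' @param central_slices Indices of the central B-scans; default the middle 32.
#' @return Macular curvature `mc` (rows/column^2, positive = bowl concave
#'   toward the vitreous).
#' @export
fit_macular_curvature <- function(rpe, central_slices = NULL) {
  stopifnot(is.matrix(rpe))
  n_s <- nrow(rpe); W <- ncol(rpe)
  if (is.null(central_slices)) {
    mid <- n_s %/% 2L
    central_slices <- (mid - 15L):(mid + 16L)
  }
  stopifnot(all(central_slices >= 1L), all(central_slices <= n_s))
  x_all <- seq_len(W) - (W + 1) / 2
  coefs <- vapply(central_slices, function(s) {
    y <- rpe[s, ]
    ok <- is.finite(y)
    if (mean(ok) < 0.9) return(NA_real_)
    x <- x_all[ok]
    -unname(coef(lm(y[ok] ~ x + I(x^2)))[3])
  }, numeric(1))
  if (sum(is.na(coefs)) > 3L)
    stop_qc("more than 3 central B-scans unusable for macular curvature.",
            "foveapit_qc_error")
  median(coefs, na.rm = TRUE)
}

#' Quantify one OCT volume: foveal curvature, macular curvature, thickness
#'
#' Runs the full measurement pipeline on a volume: per-B-scan A* segmentation,
#' fovea center localization on the thickness map, center point retinal
#' thickness, foveal curvature (quadratic fit over +/-12 columns at the center
#' slice) and macular curvature (median over the 32 central B-scans). Any QC
#' failure yields a record with `NA` measures and the failure reason.
#'
#' @param volume An `oct_volume` (128 B-scans of 512 A-scans).
#' @param params [segment_params()] for the boundary search.
#' @param window Foveal fit half-width (columns).
#' @return A one-row tibble: `person_id`, `eye`, `fc`, `fc_x100`, `mc`,
#'   `mc_x100`, `cprt_px`, `cprt_um`, `center_slice`, `center_column`,
#'   `n_low_confidence` (count of low-confidence B-scans) and `qc`.
#' @export
quantify_volume <- function(volume, params = segment_params(), window = 12L) {
  stopifnot(inherits(volume, "oct_volume"))
  if (length(volume$frames) != 128L)
    stop_qc("volume must contain exactly 128 B-scans.", "foveapit_shape_error")
  if (ncol(volume$frames[[1]]) != 512L)
    stop_qc("each B-scan must be 512 A-scans wide.", "foveapit_shape_error")

  record <- tibble::tibble(
    person_id = volume$person_id, eye = volume$laterality,
    fc = NA_real_, fc_x100 = NA_real_, mc = NA_real_, mc_x100 = NA_real_,
    cprt_px = NA_real_, cprt_um = NA_real_,
    center_slice = NA_integer_, center_column = NA_integer_,
    n_low_confidence = NA_integer_, qc = "ok"
  )
  res <- tryCatch({
    sweep_params <- params
    sweep_params$refine <- "parabolic" # fast sweep; re-refined where it matters
    seg <- segment_volume(volume, sweep_params)
    center <- locate_fovea_center(seg, edge_margin = window)
    # model-based sub-pixel re-refinement of the center B-scan boundaries,
    # where the curvature and thickness measures are read off
    cimg <- volume$frames[[center$slice]]
    ilm_c <- suppress_trace_outliers(
      refine_boundary_model(cimg, round(seg$ilm[center$slice, ])))
    rpe_c <- suppress_trace_outliers(
      refine_boundary_model(cimg, round(seg$rpe[center$slice, ])))
    cprt <- compute_cprt(ilm_c, rpe_c, center, axial_scale = volume$axial_scale)
    fc <- fit_foveal_curvature(ilm_c, center$column, window)
    mc <- fit_macular_curvature(seg$rpe)
    record$fc <- fc; record$fc_x100 <- 100 * fc
    record$mc <- mc; record$mc_x100 <- 100 * mc
    record$cprt_px <- cprt$cprt_px; record$cprt_um <- cprt$cprt_um
    record$center_slice <- center$slice; record$center_column <- center$column
    record$n_low_confidence <- sum(seg$qc != "ok")
    record
  }, foveapit_qc_error = function(e) {
    record$qc <- conditionMessage(e); record
  }, foveapit_boundary_error = function(e) {
    record$qc <- conditionMessage(e); record
  })
  res
}

#' Tertile-ordering validation of the curvature pipeline
#'
#' Emulates the grading exercise used to validate automated foveal curvature:
#' assemble `n_sets` sets of three scans, one drawn from each ground-truth
#' curvature tertile, and count the sets in which the pipeline's curvature
#' values rank the three scans consistently with their tertile membership.
#' Sets with tied pipeline values are counted incorrect and flagged.
#'
#' @param records A data frame with columns `fc_true` (ground truth) and
#'   `fc_est` (pipeline output), one row per eye/scan (at least 9 rows).
#' @param n_sets Number of sets to assemble (10 per protocol).
#' @param seed Seed for the set draws.
#' @return A list with `n_correct` (0..`n_sets`) and `sets`, a tibble with one
#'   row per set (`set`, member row indices, `correct`, `tied`).
#' @export
tertile_ordering_validation <- function(records, n_sets = 10L, seed = NULL) {
  stopifnot(all(c("fc_true", "fc_est") %in% names(records)), nrow(records) >= 9)
  q <- quantile(records$fc_true, c(1, 2) / 3, type = 7)
  if (q[1] >= q[2])
    stop_qc("ground-truth curvature tertiles are not separated.",
            "foveapit_validation_error")
  tert <- 1L + (records$fc_true > q[1]) + (records$fc_true > q[2])
  pools <- split(seq_len(nrow(records)), tert)
  if (length(pools) < 3L)
    stop_qc("ground-truth curvature tertiles are not separated.",
            "foveapit_validation_error")
  sets <- with_seed(seed, lapply(seq_len(n_sets), function(i) {
    vapply(pools, function(p) if (length(p) == 1L) p else sample(p, 1L),
           integer(1))
  }))
  out <- purrr::map_dfr(seq_len(n_sets), function(i) {
    idx <- sets[[i]]
    est <- records$fc_est[idx]
    tied <- anyDuplicated(est) > 0 || any(!is.finite(est))
    correct <- !tied && all(diff(est) > 0)
    tibble::tibble(set = i, low = idx[1], mid = idx[2], high = idx[3],
                   correct = correct, tied = tied)
  })
  list(n_correct = sum(out$correct), sets = out)
}
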