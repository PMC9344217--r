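#' Segmentation parameters
#'
#' Tuning knobs for the A* boundary search. The cost of a boundary path is the
#' sum of per-pixel costs (one minus the normalized signed vertical gradient,
#' oriented dark-to-bright for the ILM and bright-to-dark for the RPE) plus a
#' smoothness penalty `lambda * |row jump|` per column step.
#'
#' @param lambda Smoothness penalty per row of vertical jump between adjacent
#'   columns. Default 0.1.
#' @param max_jump Maximum row jump per column step (limits shortcuts across
#'   vessel shadows). Default 15.
#' @param smooth_sigma Gaussian pre-smoothing sigma (pixels) applied before
#'   gradients are taken, for speckle robustness. Default 1.
#' @param grad_tol Minimum gradient dynamic range, as a fraction of the image
#'   maximum, below which the image is declared featureless. Default 1e-4.
#' @param refine Sub-pixel refinement: `"model"` (default) fits the two-level
#'   partial-volume edge model to log-intensities around each path row —
#'   statistically matched to multiplicative speckle and exact on clean
#'   renders; `"parabolic"` interpolates the raw-gradient peak (faster,
#'   noisier).
#' @return A list of class `segment_params`.
#' @export
segment_params <- function(lambda = 0.1, max_jump = 15L, smooth_sigma = 1,
                           grad_tol = 1e-4, refine = c("model", "parabolic")) {
  stopifnot(lambda >= 0, max_jump >= 1, smooth_sigma >= 0, grad_tol >= 0)
  structure(list(lambda = lambda, max_jump = as.integer(max_jump),
                 smooth_sigma = smooth_sigma, grad_tol = grad_tol,
                 refine = match.arg(refine)),
            class = "segment_params")
}

# Separable Gaussian blur with edge replication.
gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_along(k)) { # vertical pass
    idx <- pmin(pmax(seq_len(H) + (i - r - 1L), 1L), H)
    out <- out + k[i] * img[idx, , drop = FALSE]
  }
  out2 <- matrix(0, H, W)
  for (i in seq_along(k)) { # horizontal pass
    idx <- pmin(pmax(seq_len(W) + (i - r - 1L), 1L), W)
    out2 <- out2 + k[i] * out[, idx, drop = FALSE]
  }
  out2
}

# Central-difference vertical gradient (positive = intensity increasing
# downward, i.e. a dark-to-bright edge).
vertical_gradient <- function(img) {
  H <- nrow(img)
  up <- img[pmax(seq_len(H) - 1L, 1L), , drop = FALSE]
  dn <- img[pmin(seq_len(H) + 1L, H), , drop = FALSE]
  (dn - up) / 2
}

# Cost image for one surface polarity: 1 - gradient rescaled to [0, 1].
gradient_cost <- function(g) {
  rng <- range(g)
  1 - (g - rng[1]) / (rng[2] - rng[1])
}

#' Segment the retina in one B-scan by A* shortest-path boundary search
#'
#' Finds the ILM as the minimum-cost left-to-right path on a dark-to-bright
#' vertical-gradient cost image and the RPE on the bright-to-dark counterpart,
#' each path constrained to one column per step with a bounded row jump. Both
#' paths are globally optimal for the declared cost function (sum of node
#' costs plus `lambda * |row jump|`). Boundary rows are then refined to
#' sub-pixel precision by parabolic interpolation of the raw vertical gradient
#' around each path row, and the segmentation mask is the band between the two
#' refined boundaries.
#'
#' If the refined boundaries cross anywhere, the ILM is clamped to one row
#' above the RPE and the scan is flagged `"low_confidence"`.
#'
#' @param bscan Numeric matrix (rows x columns) of non-negative intensities,
#'   at least 32 x 32.
#' @param params A [segment_params()] object.
#' @return An object of class `oct_segmentation`: `mask` (logical matrix,
#'   `TRUE` between ILM and RPE inclusive), sub-pixel `ilm` and `rpe` row
#'   vectors, the integer A* paths and costs (`ilm_path`, `rpe_path`,
#'   `ilm_cost`, `rpe_cost`), and a per-scan `qc` flag (`"ok"` or
#'   `"low_confidence"`).
#' @examples
#' sc <- scene_truth(noise_sigma = 0)
#' seg <- astar_segment(render_bscan(sc, 64))
#' seg$qc
#' @export
astar_segment <- function(bscan, params = segment_params()) {
  stopifnot(is.matrix(bscan), is.numeric(bscan))
  if (nrow(bscan) < 32L || ncol(bscan) < 32L)
    stop_qc("B-scan must be at least 32 x 32 pixels.", "foveapit_shape_error")
  if (any(bscan < 0)) stop_qc("intensities must be non-negative.",
                              "foveapit_validation_error")
  if (!inherits(params, "segment_params")) params <- do.call(segment_params, params)

  g_raw <- vertical_gradient(bscan)
  g <- vertical_gradient(gauss_smooth(bscan, params$smooth_sigma))
  if (diff(range(g)) <= max(1e-12, params$grad_tol * max(abs(bscan))))
    stop_qc("no usable vertical gradient: boundary not found.",
            "foveapit_boundary_error")

  ilm_sp <- astar_path_cpp(gradient_cost(g), params$lambda, params$max_jump)
  rpe_sp <- astar_path_cpp(gradient_cost(-g), params$lambda, params$max_jump)

  if (params$refine == "model") {
    ilm <- refine_boundary_model(bscan, ilm_sp$rows)
    rpe <- refine_boundary_model(bscan, rpe_sp$rows)
  } else {
    ilm <- refine_subpixel(g_raw, ilm_sp$rows)
    rpe <- refine_subpixel(-g_raw, rpe_sp$rows)
  }
  ilm <- suppress_trace_outliers(ilm)
  rpe <- suppress_trace_outliers(rpe)

  qc <- "ok"
  crossing <- ilm > rpe - 1
  if (any(crossing)) {
    ilm[crossing] <- rpe[crossing] - 1
    qc <- "low_confidence"
  }

  structure(list(
    mask = trace_band_mask(ilm, rpe, nrow(bscan)),
    ilm = ilm, rpe = rpe,
    ilm_path = ilm_sp$rows, rpe_path = rpe_sp$rows,
    ilm_cost = ilm_sp$cost, rpe_cost = rpe_sp$cost,
    qc = qc, params = params
  ), class = "oct_segmentation")
}

# Sub-pixel boundary refinement: within `radius` rows of the path row, find
# the local maximum of the polarity-signed raw gradient and interpolate its
# parabolic vertex. Exact for the partial-volume edge profile the renderer
# produces (the 3-point parabola through a linear-blend edge peaks at the
# continuous boundary coordinate).
refine_subpixel <- function(g_signed, path_rows, radius = 2L) {
  H <- nrow(g_signed)
  vapply(seq_along(path_rows), function(j) {
    r0 <- path_rows[j]
    lo <- max(2L, r0 - radius); hi <- min(H - 1L, r0 + radius)
    if (lo > hi) return(as.numeric(r0))
    win <- g_signed[lo:hi, j]
    r <- lo + which.max(win) - 1L
    a <- g_signed[r - 1L, j]; b <- g_signed[r, j]; cc <- g_signed[r + 1L, j]
    den <- a - 2 * b + cc
    if (den < -1e-12) {
      delta <- 0.5 * (a - cc) / den
      r + max(-0.5, min(0.5, delta))
    } else as.numeric(r)
  }, numeric(1))
}

# Replace isolated trace columns that deviate from a running median by more
# than `tol` rows (extreme speckle can capture single columns). A no-op on
# clean traces: a smooth boundary never strays that far from its own median.
suppress_trace_outliers <- function(rows, window = 9L, tol = 1.5) {
  med <- stats::runmed(rows, window, endrule = "median")
  out <- abs(rows - med) > tol
  rows[out] <- med[out]
  rows
}

# Model-based sub-pixel boundary refinement.
#
# The renderer's column profile is a two-level partial-volume edge: intensity
# = above + (below - above) * clip(r + 0.5 - pos, 0, 1). With multiplicative
# speckle the log-intensity noise is homoscedastic, so the edge position is
# re-estimated per column by least squares on log-intensities over a window
# of rows around the A* path row, with the two plateau levels estimated from
# robust medians just outside the window. A coarse grid over the offset is
# sharpened by parabolic interpolation of the loss; on a noiseless render the
# loss vanishes at the true position, making the estimate exact.
refine_boundary_model <- function(img, path_rows,
                                  fit_halfwidth = 8L,
                                  level_offsets = 9:12,
                                  delta_grid = seq(-5, 5, by = 0.2)) {
  H <- nrow(img); W <- ncol(img)
  r0 <- as.integer(path_rows)
  margin <- max(level_offsets)
  usable <- r0 - margin >= 1L & r0 + margin <= H
  out <- as.numeric(r0)
  if (!any(usable)) return(out)
  jj <- which(usable)
  r0u <- r0[jj]; nu <- length(jj)

  k <- (-fit_halfwidth):fit_halfwidth
  pick <- function(offsets) {
    idx <- outer(offsets, r0u, `+`)
    matrix(img[cbind(as.vector(idx), rep(jj, each = length(offsets)))],
           length(offsets), nu)
  }
  li <- log(pmax(pick(k), 1e-8))
  med4 <- function(m) (colSums(m) - apply(m, 2, max) - apply(m, 2, min)) / 2
  above <- pmax(med4(pick(-level_offsets)), 1e-8)
  below <- pmax(med4(pick(level_offsets)), 1e-8)
  contrast <- below - above

  # Negative gamma log-likelihood of the log-residuals d = log(I) - log(model):
  # for multiplicative Gamma(k, 1/k) speckle, -loglik is proportional to
  # sum(exp(d) - d); its minimum at d = 0 also makes the noiseless fit exact.
  sse_at <- function(delta) { # delta: scalar or per-column vector
    cov <- pmin(pmax(outer(k, rep_len(delta, nu), `-`) + 0.5, 0), 1)
    model_log <- log(pmax(matrix(above, length(k), nu, byrow = TRUE) +
                            cov * matrix(contrast, length(k), nu, byrow = TRUE),
                          1e-8))
    d <- li - model_log
    colSums(exp(d) - d)
  }
  # stage 1: coarse common grid
  sse1 <- vapply(delta_grid, sse_at, numeric(nu))
  if (nu == 1L) sse1 <- matrix(sse1, 1L)
  delta <- delta_grid[max.col(-sse1, ties.method = "first")]
  # stage 2: fine per-column grid around the coarse minimum
  fine <- seq(-0.25, 0.25, by = 0.01)
  sse2 <- vapply(fine, function(f) sse_at(delta + f), numeric(nu))
  if (nu == 1L) sse2 <- matrix(sse2, 1L)
  delta <- delta + fine[max.col(-sse2, ties.method = "first")]
  # indifferent loss (no usable edge contrast): keep the path row
  delta[abs(contrast) < 0.05 * (above + below)] <- 0
  out[jj] <- r0u + delta
  out
}

#' @export
print.oct_segmentation <- function(x, ...) {
  cat("<oct_segmentation> ", ncol(x$mask), " columns, qc: ", x$qc, "\n", sep = "")
  cat(sprintf("  path costs: ILM %.3f, RPE %.3f\n", x$ilm_cost, x$rpe_cost))
  invisible(x)
}

#' Render one clean or noisy B-scan from a scene
#'
#' Convenience wrapper around the volume renderer for a single slice; noise
#' (if any) uses the scene's recorded seed offset by the slice index.
#'
#' @param truth A [scene_truth()] object.
#' @param slice Slice (B-scan) index.
#' @param noisy Apply the scene's speckle model? Defaults to `TRUE` when
#'   `truth$noise_sigma > 0`.
#' @return Intensity matrix.
#' @export
render_bscan <- function(truth, slice, noisy = truth$noise_sigma > 0) {
  stopifnot(inherits(truth, "scene_truth"))
  if (!noisy) return(render_bscan_clean(truth, slice, noisy = FALSE))
  seed <- if (is.null(truth$seed)) NULL else truth$seed + slice
  with_seed(seed, render_bscan_clean(truth, slice, noisy = TRUE))
}

#' Extract a boundary trace from a segmentation or mask
#'
#' `extract_ilm()` returns the top (smallest-row) retina boundary,
#' `extract_rpe()` the bottom (largest-row) one. Applied to an
#' [astar_segment()] result they return its sub-pixel refined traces; applied
#' to a plain logical mask they take the per-column extreme `TRUE` row, and
#' columns with no `TRUE` pixels are linearly interpolated from their valid
#' neighbors and flagged.
#'
#' @param x An `oct_segmentation` object or a logical mask matrix.
#' @return A `boundary_trace` tibble with columns `column`, `row`, `valid`,
#'   `interpolated`, and an attribute `surface` (`"ILM"` or `"RPE"`).
#' @export
extract_ilm <- function(x) extract_boundary(x, "ILM")

#' @rdname extract_ilm
#' @export
extract_rpe <- function(x) extract_boundary(x, "RPE")

extract_boundary <- function(x, surface) {
  if (inherits(x, "oct_segmentation")) {
    rows <- if (surface == "ILM") x$ilm else x$rpe
    tr <- tibble::tibble(column = seq_along(rows), row = rows,
                         valid = TRUE, interpolated = FALSE)
    return(structure(tr, surface = surface, class = c("boundary_trace", class(tr))))
  }
  stopifnot(is.matrix(x), is.logical(x))
  W <- ncol(x)
  occupied <- colSums(x) > 0
  if (!any(occupied))
    stop_qc("mask is empty everywhere.", "foveapit_boundary_error")
  if (mean(occupied) < 0.5)
    stop_qc("mask is empty in more than half the columns.",
            "foveapit_boundary_error")
  pick <- if (surface == "ILM") function(v) which(v)[1]
          else function(v) { w <- which(v); w[length(w)] }
  rows <- rep(NA_real_, W)
  rows[occupied] <- vapply(which(occupied), function(j) as.numeric(pick(x[, j])),
                           numeric(1))
  interp <- !occupied
  if (any(interp)) {
    rows[interp] <- stats::approx(which(occupied), rows[occupied],
                                  xout = which(interp), rule = 2)$y
  }
  tr <- tibble::tibble(column = seq_len(W), row = rows,
                       valid = occupied, interpolated = interp)
  structure(tr, surface = surface, class = c("boundary_trace", class(tr)))
}

#' Intersection over union of two segmentation masks
#'
#' @param pred,truth Logical mask matrices of identical shape (or objects with
#'   a `$mask` element, e.g. [astar_segment()] results).
#' @return IoU in \[0, 1\]; two empty masks count as identical (IoU 1).
#' @export
miou <- function(pred, truth) {
  if (!is.matrix(pred)) pred <- pred$mask
  if (!is.matrix(truth)) truth <- truth$mask
  stopifnot(identical(dim(pred), dim(truth)))
  un <- sum(pred | truth)
  if (un == 0) return(1)
  sum(pred & truth) / un
}

#' Segment every B-scan of a volume
#'
#' @param volume An `oct_volume`.
#' @param params A [segment_params()] object.
#' @param keep_masks Keep the per-scan masks (memory-heavy)? Default `FALSE`;
#'   the boundary traces are always kept.
#' @return An object of class `oct_volume_segmentation`: `ilm` and `rpe`
#'   (`n_slices x width` matrices of sub-pixel boundary rows), per-scan `qc`
#'   character vector, and optionally `masks` (a list).
#' @export
segment_volume <- function(volume, params = segment_params(), keep_masks = FALSE) {
  stopifnot(inherits(volume, "oct_volume"))
  segs <- lapply(volume$frames, astar_segment, params = params)
  structure(list(
    ilm = do.call(rbind, lapply(segs, `[[`, "ilm")),
    rpe = do.call(rbind, lapply(segs, `[[`, "rpe")),
    qc = vapply(segs, `[[`, character(1), "qc"),
    masks = if (keep_masks) lapply(segs, `[[`, "mask")
  ), class = "oct_volume_segmentation")
}
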