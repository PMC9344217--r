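#' Render a synthetic OCT volume from a ground-truth scene
#'
#' Rasterizes the scene's three intensity bands (dark vitreous above the ILM,
#' bright retina between ILM and RPE, dimmer choroid below) with exact
#' partial-volume blending at the two boundaries, then applies multiplicative
#' gamma-distributed speckle with unit mean and standard deviation
#' `truth$noise_sigma`. Rendering is deterministic for a fixed seed.
#'
#' @param truth A [scene_truth()] object.
#' @param seed Integer seed for the speckle noise; overrides `truth$seed`.
#' @param person_id,eye_id,laterality Identifiers carried on the volume.
#' @return An object of class `oct_volume`: `frames` (list of
#'   `height x width` intensity matrices, one per B-scan), pixel scales and
#'   identifiers. The paired `scene_truth` is attached as attribute `"truth"`.
#' @examples
#' sc <- scene_truth(noise_sigma = 0)
#' vol <- generate_volume(sc)
#' range(vol$frames[[64]])
#' @export
generate_volume <- function(truth, seed = truth$seed,
                            person_id = "P0001", eye_id = "P0001_R",
                            laterality = c("right", "left")) {
  stopifnot(inherits(truth, "scene_truth"))
  laterality <- match.arg(laterality)
  frames <- with_seed(seed, lapply(seq_len(truth$n_slices), function(s) {
    render_bscan_clean(truth, s, noisy = TRUE)
  }))
  structure(list(
    frames = frames,
    lateral_scale = truth$lateral_mm / truth$width,
    slice_scale = truth$lateral_mm / truth$n_slices,
    axial_scale = truth$axial_scale_um,
    person_id = person_id, eye_id = eye_id, laterality = laterality
  ), class = "oct_volume", truth = truth)
}

#' @export
print.oct_volume <- function(x, ...) {
  cat("<oct_volume> ", length(x$frames), " B-scans of ",
      nrow(x$frames[[1]]), " x ", ncol(x$frames[[1]]),
      " (", x$eye_id, ", ", x$laterality, " eye)\n", sep = "")
  invisible(x)
}

# Clean (and optionally speckled) render of one B-scan.
# Pixel r covers rows [r-0.5, r+0.5); intensity is the coverage-weighted
# mixture of the three bands, so the intensity ramp crosses its midpoint
# exactly at the continuous boundary coordinate.
render_bscan_clean <- function(truth, slice, noisy = FALSE) {
  H <- truth$height; W <- truth$width
  ilm <- truth$ilm[slice, ]; rpe <- truth$rpe[slice, ]
  ints <- truth$intensities
  r <- matrix(seq_len(H), H, W)
  ilm_m <- matrix(ilm, H, W, byrow = TRUE)
  rpe_m <- matrix(rpe, H, W, byrow = TRUE)
  cov_vit <- pmin(pmax(ilm_m - (r - 0.5), 0), 1)
  cov_cho <- pmin(pmax((r + 0.5) - rpe_m, 0), 1)
  img <- ints[["vitreous"]] * cov_vit + ints[["choroid"]] * cov_cho +
    ints[["retina"]] * (1 - cov_vit - cov_cho)
  if (noisy && truth$noise_sigma > 0) {
    shape <- 1 / truth$noise_sigma^2
    img <- img * matrix(rgamma(H * W, shape = shape, scale = 1 / shape), H, W)
  }
  img
}

#' Generate standalone synthetic B-scans with per-scan ground truth
#'
#' Draws `n` independent foveal scenes whose curvature, center-point thickness
#' and pit position vary across scans, and renders the pit-center B-scan of
#' each. This is the held-out-scan generator used for segmentation validation:
#' each scan comes with its exact boundary truth and truth mask.
#'
#' Per-scan truth is sampled to match the population the scanner cohort
#' reports: foveal curvature `N(0.0725, 0.02)` (truncated to the renderable
#' range), CPRT around 87 px (about 226 um at 2.6 um/row), and a jittered pit
#' column.
#'
#' @param n Number of B-scans.
#' @param seed Integer seed; each scan derives its own child seed.
#' @param fc_mean,fc_sd Mean/SD of the true foveal curvature distribution.
#' @param ... Further arguments passed to [scene_truth()] (e.g. `noise_sigma`).
#' @return A list of `n` elements, each with `image`, `truth`
#'   (the `scene_truth`), `slice` (the rendered slice index), `ilm`, `rpe`
#'   (truth rows for that slice) and `mask` (truth retina mask).
#' @export
generate_bscans <- function(n, seed = NULL,
                            fc_mean = 0.0725, fc_sd = 0.02, ...) {
  stopifnot(n >= 1)
  seeds <- child_seeds(seed, n)
  fixed <- list(...)
  lapply(seq_len(n), function(i) {
    with_seed(seeds[i], {
      draw <- sample_scene_params(fc_mean, fc_sd)
      args <- modifyList(c(draw, list(seed = seeds[i])), fixed)
      truth <- do.call(scene_truth, args)
      slice <- truth$pit_center[["slice"]]
      img <- render_bscan_clean(truth, slice, noisy = TRUE)
      list(image = img, truth = truth, slice = slice,
           ilm = truth$ilm[slice, ], rpe = truth$rpe[slice, ],
           mask = truth_mask(truth, slice))
    })
  })
}

# Draw coupled per-scan truth parameters. Rim thickness and the pit's extra
# (beyond-quadratic) depth are sampled; CPRT is derived as rim minus total pit
# depth, so steeper pits are thinner at the center (the inverse FC-CPRT
# coupling seen in real cohorts) and every draw satisfies the scene
# invariants by construction.
sample_scene_params <- function(fc_mean = 0.0725, fc_sd = 0.02,
                                rim_mean = 118, rim_sd = 5,
                                extra_depth_mean = 12, extra_depth_sd = 4,
                                a_macula = 0.0021, quad_halfwidth = 16L) {
  a_f <- truncnorm1(fc_mean, fc_sd, 0.01, 0.115)
  rim <- truncnorm1(rim_mean, rim_sd, 100, 135)
  extra <- truncnorm1(extra_depth_mean, extra_depth_sd, 1, 30)
  cprt <- rim - (a_f - a_macula) * quad_halfwidth^2 - extra
  list(a_fovea = a_f, a_macula = a_macula, cprt_px = cprt,
       rim_thickness_px = rim, quad_halfwidth = quad_halfwidth,
       pit_center = c(64L, sample(200:312, 1L)))
}

# One draw from a truncated normal (rejection; bounds are loose).
truncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}
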