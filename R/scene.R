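#' Define a synthetic OCT scene with known ground-truth boundaries
#'
#' Builds the ground truth for a synthetic macular OCT volume: an RPE surface
#' shaped as a smooth bowl (quadratic in both the A-scan and the B-scan
#' direction) and an ILM surface equal to the RPE minus a thickness field that
#' carries a foveal pit. The pit is exactly quadratic in the column coordinate
#' within `quad_halfwidth` columns of its center and blends into a flat rim
#' with a cosine taper, so that a quadratic fitted over the standard +/-12
#' column window recovers `a_fovea` exactly in the noiseless limit.
#'
#' Row indices increase downward (toward the choroid), so a pit is a row
#' *maximum* of the ILM and curvatures are reported sign-adjusted (positive =
#' normal pit / bowl). All indices are 1-based.
#'
#' @param a_fovea Foveal curvature: leading coefficient (rows/column^2) of the
#'   ILM quadratic at the pit, sign-adjusted so a normal pit is positive.
#'   The population mean in healthy adults is about 0.0725 with SD about 0.02.
#'   `a_fovea = 0` (with `a_macula = 0`) renders a flat ILM.
#' @param a_macula Macular curvature: sign-adjusted leading coefficient
#'   (rows/column^2) of the per-B-scan RPE quadratic; about 0.0021 on average.
#' @param pit_center Integer `c(slice, column)` of the pit (thinnest retina).
#' @param cprt_px Retinal thickness in pixels at the pit center (ILM-to-RPE).
#' @param rim_thickness_px Retinal thickness away from the pit, pixels.
#' @param noise_sigma Speckle scale: standard deviation of the multiplicative
#'   gamma noise applied to the clean render (0 = noiseless).
#' @param height,n_slices,width Frame dimensions; the scanner protocol
#'   emulated here acquires 128 B-scans of 512 A-scans over 6 x 6 mm.
#' @param axial_scale_um Axial pixel pitch, micrometers per row.
#' @param lateral_mm Lateral extent of the scan, mm (same in both directions).
#' @param rpe_center_row Row of the RPE at the volume center.
#' @param quad_halfwidth Half-width (columns) of the exactly quadratic pit zone.
#' @param taper_halfwidth Column offset at which the pit has fully blended
#'   into the rim.
#' @param slice_extent Half-extent of the pit across slices (B-scans).
#' @param intensities Named vector of mean intensities for the three bands:
#'   `vitreous` (above ILM), `retina` (ILM..RPE), `choroid` (below RPE).
#' @param seed Integer seed recorded with the truth (used by renderers).
#'
#' @return An object of class `scene_truth`: ground-truth `ilm` and `rpe`
#'   surfaces (`n_slices x width` matrices of row coordinates), the generating
#'   parameters, and `cprt_true_px`, the thickness at the pit center.
#' @seealso [generate_volume()], [generate_bscans()]
#' @export
scene_truth <- function(a_fovea = 0.0725,
                        a_macula = 0.0021,
                        pit_center = c(64L, 256L),
                        cprt_px = 87,
                        rim_thickness_px = 118,
                        noise_sigma = 0.2,
                        height = 650L,
                        n_slices = 128L,
                        width = 512L,
                        axial_scale_um = 2.6,
                        lateral_mm = 6,
                        rpe_center_row = 420,
                        quad_halfwidth = 16L,
                        taper_halfwidth = 40L,
                        slice_extent = 6L,
                        intensities = c(vitreous = 30, retina = 160, choroid = 60),
                        seed = NULL) {
  fail <- function(msg) stop_qc(msg, "foveapit_validation_error")

  if (!is.numeric(a_fovea) || length(a_fovea) != 1L || a_fovea < 0)
    fail("`a_fovea` must be a single non-negative number.")
  if (!is.numeric(a_macula) || length(a_macula) != 1L || a_macula < 0)
    fail("`a_macula` must be a single non-negative number.")
  if (length(pit_center) != 2L) fail("`pit_center` must be c(slice, column).")
  if (axial_scale_um <= 0 || lateral_mm <= 0) fail("scales must be positive.")
  if (noise_sigma < 0) fail("`noise_sigma` must be >= 0.")
  if (cprt_px < 1) fail("`cprt_px` must be >= 1 pixel.")
  if (rim_thickness_px <= cprt_px && a_fovea > 0)
    fail("`rim_thickness_px` must exceed `cprt_px` when a pit is present.")
  if (quad_halfwidth < 13L)
    fail("`quad_halfwidth` must cover the 12-column fit window (>= 13).")
  if (taper_halfwidth <= quad_halfwidth)
    fail("`taper_halfwidth` must exceed `quad_halfwidth`.")

  s0 <- as.integer(pit_center[[1]]); c0 <- as.integer(pit_center[[2]])
  if (s0 < 1L || s0 > n_slices || c0 < 1L || c0 > width)
    fail("`pit_center` outside volume bounds.")

  has_pit <- a_fovea > 0
  a_pit <- if (has_pit) a_fovea - a_macula else 0
  if (has_pit && a_pit < 0)
    fail("`a_fovea` must be >= `a_macula` when a pit is present.")
  depth <- if (has_pit) rim_thickness_px - cprt_px else 0
  if (has_pit && depth < a_pit * quad_halfwidth^2)
    fail(sprintf(
      "pit depth %.1f px cannot carry curvature %.4f over +/-%d columns (needs >= %.1f px).",
      depth, a_fovea, quad_halfwidth, a_pit * quad_halfwidth^2))

  # RPE bowl: quadratic in columns (reported MC) and in slices (same physical
  # curvature, scaled by the slice/column pitch ratio squared).
  col_pitch_um <- lateral_mm * 1000 / width
  slice_pitch_um <- lateral_mm * 1000 / n_slices
  a_mac_slice <- a_macula * (slice_pitch_um / col_pitch_um)^2

  cols <- seq_len(width); slices <- seq_len(n_slices)
  c_mid <- (width + 1) / 2; s_mid <- (n_slices + 1) / 2
  rpe <- outer(-a_mac_slice * (slices - s_mid)^2,
               -a_macula * (cols - c_mid)^2, `+`) + rpe_center_row

  # Thickness field: flat rim minus a pit bump separable in slice x column.
  pit_col <- numeric(width)
  if (has_pit) {
    dcol <- abs(cols - c0)
    quad <- dcol <= quad_halfwidth
    pit_col[quad] <- depth - a_pit * dcol[quad]^2
    h_rem <- depth - a_pit * quad_halfwidth^2
    tap <- dcol > quad_halfwidth & dcol <= taper_halfwidth
    pit_col[tap] <- h_rem * 0.5 *
      (1 + cos(pi * (dcol[tap] - quad_halfwidth) / (taper_halfwidth - quad_halfwidth)))
  }
  g_slice <- numeric(n_slices)
  ds <- abs(slices - s0)
  g_slice[ds < slice_extent] <- 0.5 * (1 + cos(pi * ds[ds < slice_extent] / slice_extent))
  thickness <- rim_thickness_px - outer(g_slice, pit_col)

  ilm <- rpe - thickness

  if (any(thickness < 1)) fail("invalid scene: ILM would cross the RPE.")
  if (min(ilm) < 3 || max(rpe) > height - 3)
    fail("surfaces leave the frame; enlarge `height` or adjust geometry.")

  structure(list(
    ilm = ilm, rpe = rpe,
    a_fovea_true = a_fovea, a_macula_true = a_macula,
    pit_center = c(slice = s0, column = c0),
    cprt_true_px = unname(thickness[s0, c0]),
    noise_sigma = noise_sigma, seed = seed,
    height = as.integer(height), n_slices = as.integer(n_slices),
    width = as.integer(width),
    axial_scale_um = axial_scale_um, lateral_mm = lateral_mm,
    intensities = intensities,
    params = list(rim_thickness_px = rim_thickness_px, cprt_px = cprt_px,
                  rpe_center_row = rpe_center_row,
                  quad_halfwidth = quad_halfwidth,
                  taper_halfwidth = taper_halfwidth,
                  slice_extent = slice_extent)
  ), class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("<scene_truth> ", x$n_slices, " slices x ", x$height, " rows x ",
      x$width, " cols\n", sep = "")
  cat(sprintf("  FC truth %.4f (x100 = %.2f), MC truth %.4f, CPRT %.1f px (%.1f um)\n",
              x$a_fovea_true, 100 * x$a_fovea_true, x$a_macula_true,
              x$cprt_true_px, x$cprt_true_px * x$axial_scale_um))
  cat(sprintf("  pit at slice %d, column %d; speckle sigma %.2f\n",
              x$pit_center[["slice"]], x$pit_center[["column"]], x$noise_sigma))
  invisible(x)
}

#' Ground-truth retina mask for one B-scan
#'
#' Pixels whose centers lie within the closed ILM-to-RPE band. The same
#' rasterization rule is used for predicted masks, so a perfect boundary
#' estimate yields IoU 1.
#'
#' @param truth A [scene_truth()] object.
#' @param slice B-scan index (1-based).
#' @return Logical `height x width` matrix.
#' @export
truth_mask <- function(truth, slice) {
  stopifnot(inherits(truth, "scene_truth"))
  trace_band_mask(truth$ilm[slice, ], truth$rpe[slice, ], truth$height)
}

# Rasterize a boundary pair into a mask: rows r with ilm <= r <= rpe.
trace_band_mask <- function(ilm, rpe, height) {
  w <- length(ilm)
  m <- matrix(FALSE, height, w)
  top <- pmax(1L, as.integer(ceiling(ilm - 1e-9)))
  bot <- pmin(height, as.integer(floor(rpe + 1e-9)))
  ok <- which(is.finite(ilm) & is.finite(rpe) & top <= bot)
  for (j in ok) m[top[j]:bot[j], j] <- TRUE
  m
}
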