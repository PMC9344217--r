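test_that("fovea center is the thinnest-retina point, with the centroid tie-break", {
  fs <- flat_surfaces()
  fs$ilm[64, 256] <- fs$ilm[64, 256] + 15 # unique thinnest point
  ctr <- locate_fovea_center(fs$ilm, fs$rpe)
  expect_equal(c(ctr$slice, ctr$column), c(64, 256))

  fs2 <- flat_surfaces()
  fs2$ilm[64, 255:257] <- fs2$ilm[64, 255:257] + 15 # symmetric plateau
  ctr2 <- locate_fovea_center(fs2$ilm, fs2$rpe)
  expect_equal(c(ctr2$slice, ctr2$column), c(64, 256))
})

test_that("fovea center QC failures: border minima, edge columns, invalid traces", {
  fs <- flat_surfaces()
  fs$ilm[1, 256] <- fs$ilm[1, 256] + 30
  expect_error(locate_fovea_center(fs$ilm, fs$rpe), class = "foveapit_qc_error")
  fs2 <- flat_surfaces()
  fs2$ilm[64, 5] <- fs2$ilm[64, 5] + 30
  expect_error(locate_fovea_center(fs2$ilm, fs2$rpe), class = "foveapit_qc_error")
  fs3 <- flat_surfaces()
  fs3$ilm[, 1:100] <- NA
  expect_error(locate_fovea_center(fs3$ilm, fs3$rpe), class = "foveapit_qc_error")
})

test_that("center point retinal thickness is the boundary difference times the scale", {
  r <- compute_cprt(100, 187, 1L, axial_scale = 2.6)
  expect_equal(r$cprt_px, 87)
  expect_equal(r$cprt_um, 226.2)
  r2 <- compute_cprt(100, 190, 1L, axial_scale = 1)
  expect_equal(r2$cprt_um, 90)
  expect_error(compute_cprt(100, 100, 1L), class = "foveapit_qc_error")
  expect_error(compute_cprt(120, 100, 1L), class = "foveapit_qc_error")
})

test_that("foveal curvature fit recovers exact quadratics and honors QC rules", {
  x <- 1:512
  rows <- 300 - 0.0725 * (x - 256)^2 # pit-positive convention (row-down)
  fc <- fit_foveal_curvature(rows, 256)
  expect_equal(fc, 0.0725, tolerance = 1e-12)
  expect_equal(100 * fc, 7.25, tolerance = 1e-9) # the x100 reporting scale

  expect_equal(fit_foveal_curvature(0.5 * x + 3, 256), 0, tolerance = 1e-12)

  expect_error(fit_foveal_curvature(rows, 10), class = "foveapit_qc_error")
  rows[250] <- NA
  expect_error(fit_foveal_curvature(rows, 256), class = "foveapit_qc_error")
})

test_that("curvature fit is unbiased under row noise (closed-form LS oracle)", {
  x <- -12:12
  truth <- 0.0725
  set.seed(42)
  ests <- replicate(1000, {
    y <- 300 - truth * x^2 + rnorm(25, 0, 0.5)
    fit_foveal_curvature(y, 13, window = 12L)
  })
  expect_lt(abs(mean(ests) - truth) / truth, 0.01)
  # single draw agrees with the normal-equations oracle to numerical precision
  y <- 300 - truth * x^2 + rnorm(25, 0, 0.5)
  expect_equal(fit_foveal_curvature(y, 13), -quad_ls_oracle(x, y),
               tolerance = 1e-10)
})

test_that("macular curvature is the median over central slices and is robust", {
  x <- 1:512; xc <- x - 256.5
  mk_rpe <- function(coefs) t(vapply(coefs, function(a) 400 - a * xc^2,
                                     numeric(512)))
  rpe <- mk_rpe(rep(0.0021, 128))
  expect_equal(fit_macular_curvature(rpe), 0.0021, tolerance = 1e-12)

  coefs <- rep(0.0021, 128); coefs[60] <- 0.5 # one gross outlier slice
  expect_equal(fit_macular_curvature(mk_rpe(coefs)), 0.0021, tolerance = 1e-12)

  expect_equal(fit_macular_curvature(matrix(400, 128, 512)), 0)

  # median robustness: up to 15 of 32 one-sided corruptions leave it unchanged
  coefs15 <- rep(0.0021, 128); coefs15[49:63] <- 7
  expect_equal(fit_macular_curvature(mk_rpe(coefs15)), 0.0021, tolerance = 1e-12)
  coefs16 <- rep(0.0021, 128); coefs16[49:64] <- 7
  expect_gt(fit_macular_curvature(mk_rpe(coefs16)), 0.0021 + 1e-6)

  # more than 3 unusable central slices is a QC failure
  rpe_bad <- mk_rpe(rep(0.0021, 128)); rpe_bad[49:52, 1:100] <- NA
  expect_error(fit_macular_curvature(rpe_bad), class = "foveapit_qc_error")
})

test_that("curvature and thickness are invariant to a constant vertical offset", {
  x <- 1:512
  rows <- 300 - 0.0725 * (x - 256)^2
  expect_equal(fit_foveal_curvature(rows + 117, 256),
               fit_foveal_curvature(rows, 256), tolerance = 1e-10)
  rpe <- t(vapply(1:128, function(s) 400 - 0.0021 * (x - 256.5)^2, numeric(512)))
  expect_equal(fit_macular_curvature(rpe + 50), fit_macular_curvature(rpe),
               tolerance = 1e-10)
  expect_equal(compute_cprt(150, 237, 1L)$cprt_px,
               compute_cprt(250, 337, 1L)$cprt_px)
})

test_that("quantify_volume recovers noiseless truth end-to-end and rejects bad shapes", {
  sc <- default_clean_scene()$scene
  vol <- generate_volume(sc, seed = 1)
  rec <- quantify_volume(vol)
  expect_identical(rec$qc, "ok")
  expect_lt(abs(rec$fc - sc$a_fovea_true) / sc$a_fovea_true, 1e-3)
  expect_equal(rec$fc_x100, 100 * rec$fc)
  expect_equal(rec$mc_x100, 100 * rec$mc)
  expect_lt(abs(rec$mc - sc$a_macula_true), 2e-4)
  expect_lt(abs(rec$cprt_px - sc$cprt_true_px), 1)
  expect_lte(abs(rec$center_slice - 64), 1)
  expect_lte(abs(rec$center_column - 256), 2)

  vol$frames <- vol$frames[1:100]
  expect_error(quantify_volume(vol), class = "foveapit_shape_error")
})

test_that("tertile ordering validation counts correctly ordered sets", {
  rec <- tibble::tibble(fc_true = seq(0.03, 0.11, length.out = 12),
                        fc_est = seq(0.03, 0.11, length.out = 12))
  v <- tertile_ordering_validation(rec, n_sets = 10, seed = 1)
  expect_equal(v$n_correct, 10)

  rec2 <- rec; rec2$fc_est <- rep(0.07, 12) # all tied
  v2 <- tertile_ordering_validation(rec2, n_sets = 10, seed = 1)
  expect_equal(v2$n_correct, 0)
  expect_true(all(v2$sets$tied))

  # separation below the noise floor: fewer than 10 correct over seeds
  set.seed(8)
  rec3 <- rec; rec3$fc_est <- rec$fc_true + rnorm(12, 0, 0.05)
  v3 <- tertile_ordering_validation(rec3, n_sets = 10, seed = 2)
  expect_lt(v3$n_correct, 10)

  expect_error(tertile_ordering_validation(
    tibble::tibble(fc_true = rep(1, 9), fc_est = rep(1, 9))),
    class = "foveapit_validation_error")
})
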