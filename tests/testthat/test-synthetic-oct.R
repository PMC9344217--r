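test_that("scene invariants hold and invalid parameter combinations are rejected", {
  sc <- scene_truth(seed = 1)
  expect_true(all(sc$rpe >= sc$ilm + 1))
  expect_equal(unname(sc$pit_center), c(64, 256))
  expect_gt(sc$cprt_true_px, 0)
  expect_equal(sc$cprt_true_px, 87)
  expect_equal(dim(sc$ilm), c(128, 512))

  expect_error(scene_truth(a_fovea = -0.01), class = "foveapit_validation_error")
  expect_error(scene_truth(pit_center = c(64, 600)), class = "foveapit_validation_error")
  # pit too steep for its depth: quadratic zone cannot be carried
  expect_error(scene_truth(a_fovea = 0.2), class = "foveapit_validation_error")
  expect_error(scene_truth(cprt_px = 117.9, rim_thickness_px = 118),
               class = "foveapit_validation_error")
  expect_error(scene_truth(noise_sigma = -1), class = "foveapit_validation_error")
})

test_that("renders are deterministic for a fixed seed", {
  a <- generate_bscans(1, seed = 5)[[1]]
  b <- generate_bscans(1, seed = 5)[[1]]
  expect_identical(a$image, b$image)
  expect_identical(a$truth$a_fovea_true, b$truth$a_fovea_true)
  c1 <- generate_cohort(50, seed = 9)
  c2 <- generate_cohort(50, seed = 9)
  expect_identical(c1, c2)
})

test_that("noiseless render places intensity edges exactly on the truth boundaries", {
  dc <- default_clean_scene()
  sc <- dc$scene; img <- dc$bscan
  # dark-to-bright gradient argmax per column within one row of the ILM truth
  g <- (img[3:nrow(img), ] - img[1:(nrow(img) - 2), ]) / 2
  argmax <- apply(g, 2, which.max) + 1L
  expect_true(all(abs(argmax - sc$ilm[64, ]) <= 1))
  # ILM column profile at the pit slice is exactly quadratic in the fit
  # window with leading coefficient -a_fovea (linear term allowed: the
  # macular bowl is centered half a column off the pit)
  w <- 244:268
  fit <- lm(sc$ilm[64, w] ~ poly(w, 2, raw = TRUE))
  expect_equal(unname(coef(fit)[3]), -sc$a_fovea_true, tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  # vitreous dark above, retina bright between, dimmer below
  expect_lt(img[100, 256], 60)
  expect_gt(img[round(sc$ilm[64, 256]) + 30, 256], 120)
})

test_that("a zero-curvature scene renders a flat ILM whose fitted curvature is zero", {
  sc <- scene_truth(a_fovea = 0, a_macula = 0, noise_sigma = 0, seed = 2)
  expect_equal(diff(range(sc$ilm)), 0)
  seg <- astar_segment(render_bscan(sc, 64))
  expect_lt(abs(fit_foveal_curvature(seg$ilm, 256)), 1e-8)
})

test_that("cohort generator matches its configured moments and structure", {
  coh <- generate_cohort(5000, seed = 101)
  # at most two eyes per person, right eye always present
  eyes <- table(coh$person_id)
  expect_true(all(eyes <= 2))
  expect_true(all(c("right") %in% coh$eye))
  # closed code lists with explicit missing level
  expect_true(all(coh$ethnicity %in% c("white", "black", "asian", "other",
                                       "mixed", "chinese", "prefer_not_to_say",
                                       "missing")))
  # moment check: mean and SD of fc_raw agree with the configured linear
  # predictor plus variance components within Monte-Carlo error
  lp <- foveapit:::cohort_linear_predictor(coh, cohort_effects())
  expect_lt(abs(mean(coh$fc_raw) - (0.0725 + 0.02 * mean(lp))),
            4 * 0.02 / sqrt(nrow(coh) / 2))
  expected_sd <- 0.02 * sqrt(stats::var(lp) + 0.86^2 + 0.457^2)
  expect_lt(abs(sd(coh$fc_raw) / expected_sd - 1), 0.05)
  # marginals roughly match the published cohort (92.1% white, 45.1% male)
  persons <- coh[!duplicated(coh$person_id), ]
  expect_lt(abs(mean(persons$ethnicity == "white") - 0.921), 0.02)
  expect_lt(abs(mean(persons$sex == "male") - 0.451), 0.03)
})

test_that("null cohort configuration yields a near-zero fitted person variance", {
  coh <- generate_cohort(400, effects = cohort_effects(
    sex_male = 0, ethnicity_black = 0, income_per_category = 0),
    variance_components = c(0, 0.6), seed = 77)
  coh$fc_z <- zscore_fc(coh$fc_raw)
  fit <- fit_multilevel(coh, model_spec(1, "pooled"))
  expect_lt(fit$sd_person, 0.08)
})

test_that("effect maps naming unknown covariates are rejected", {
  expect_error(cohort_effects(not_a_covariate = 1),
               class = "foveapit_validation_error")
  expect_error(generate_cohort(1), class = "foveapit_validation_error")
  expect_error(generate_cohort(10, variance_components = c(0.5, 0)),
               class = "foveapit_validation_error")
})
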