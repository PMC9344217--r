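make_small_cohort <- function(n = 300, seed = 50, ...) {
  coh <- generate_cohort(n, seed = seed, ...)
  coh$fc_z <- zscore_fc(coh$fc_raw)
  coh
}

test_that("exclusion filters drop the published disease/surgery categories in order", {
  coh <- generate_cohort(800, seed = 12)
  ex <- apply_exclusions(coh)
  expect_equal(ex$tally$reason[1:3],
               c("age-related macular degeneration", "diabetic retinopathy",
                 "macular disease"))
  expect_false(any(ex$cohort$diabetic_retinopathy))
  expect_false(any(ex$cohort$cataract_surgery))
  expect_equal(nrow(coh) - sum(ex$tally$n_excluded), nrow(ex$cohort))

  # sensitivity mode: extreme refraction and low acuity also excluded
  coh$se[1] <- -6.5; coh$va[2] <- 70
  coh$amd <- FALSE; coh$diabetic_retinopathy <- FALSE
  coh$macular_disease <- FALSE; coh$cataract_surgery <- FALSE
  coh$refractive_surgery <- FALSE; coh$corneal_graft <- FALSE
  exs <- apply_exclusions(coh, sensitivity = TRUE)
  expect_false(any(exs$cohort$se < -6 | exs$cohort$se > 6))
  expect_false(any(exs$cohort$va < 80))
  # an unremarkable eye is retained under both modes
  keep <- coh[10, ]; keep$se <- 0; keep$va <- 85
  expect_equal(nrow(apply_exclusions(keep, sensitivity = TRUE)$cohort), 1)
})

test_that("z-scoring is exact, errors on degenerate input, and is idempotent", {
  expect_equal(zscore_fc(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(zscore_fc(rep(2, 5)), class = "foveapit_validation_error")
  expect_error(zscore_fc(1), class = "foveapit_validation_error")
  x <- rnorm(50)
  z <- zscore_fc(x)
  expect_equal(z * sd(x) + mean(x), x) # round trip
  expect_equal(zscore_fc(z), z)        # idempotence
})

test_that("model specifications are nested as published", {
  m1 <- model_spec(1, "female"); m2 <- model_spec(2, "female")
  m3 <- model_spec(3, "female")
  expect_true(all(m1$fixed_effects %in% m2$fixed_effects))
  expect_true(all(m2$fixed_effects %in% m3$fixed_effects))
  expect_setequal(m1$fixed_effects,
                  c("age_decade", "ethnicity", "height_5cm", "centre"))
  expect_true("sex" %in% model_spec(1, "pooled")$fixed_effects)
})

test_that("covariate encoding applies the published reporting increments", {
  coh <- make_small_cohort(120)
  coh$age[1] <- 56; coh$cprt_um[1] <- 226; coh$va[1] <- 85
  enc <- encode_covariates(coh, model_spec(2, "pooled"))
  expect_equal(enc$data$age_decade[1], 5.6)
  expect_equal(enc$data$cprt_10[1], 22.6)
  expect_equal(enc$data$va_5[1], 17)
  expect_identical(levels(enc$data$ethnicity)[1], "white")

  coh$ethnicity[3] <- "missing"
  enc2 <- encode_covariates(coh, model_spec(1, "pooled"))
  expect_true("missing" %in% levels(enc2$data$ethnicity)) # kept, not dropped

  coh$ethnicity[4] <- "martian"
  expect_error(encode_covariates(coh, model_spec(1, "pooled")),
               class = "foveapit_validation_error")
})

test_that("with zero person-level variance the fit reduces to pooled OLS", {
  coh <- make_small_cohort(250, seed = 61, variance_components = c(0, 0.6))
  fit <- fit_multilevel(coh, model_spec(1, "pooled"))
  enc <- encode_covariates(coh, model_spec(1, "pooled"))
  ols <- lm(fc_z ~ sex + age_decade + ethnicity + height_5cm + centre,
            data = enc$data)
  common <- intersect(fit$coefs$term, names(coef(ols)))
  expect_equal(fit$coefs$estimate[match(common, fit$coefs$term)],
               unname(coef(ols)[common]), tolerance = 1e-3)
})

test_that("Satterthwaite df distinguish person-level from eye-level covariates", {
  # balanced two-eyes-per-person design, high ICC: a person-level covariate
  # has about (n_persons - p) df, far below the eye-level residual df
  set.seed(99)
  n <- 60
  d <- tibble::tibble(
    person_id = rep(sprintf("P%03d", 1:n), each = 2),
    sex = rep(sample(c("female", "male"), n, replace = TRUE), each = 2),
    x_person = rep(rnorm(n), each = 2))
  d$fc_z <- 0.4 * d$x_person + rep(rnorm(n, 0, 1), each = 2) +
    rnorm(2 * n, 0, 0.35)
  fit <- lme4::lmer(fc_z ~ x_person + (1 | person_id), data = d, REML = TRUE)
  tab <- foveapit:::satterthwaite_coefs(fit)
  df_x <- tab$df[tab$term == "x_person"]
  expect_gt(df_x, 0.6 * (n - 2))
  expect_lt(df_x, 1.4 * (n - 2)) # nowhere near the 118 eye-level residual df
  expect_true(all(tab$ci_low < tab$estimate & tab$estimate < tab$ci_high))
  # truth is covered here (calibration checked at scale in the acceptance suite)
  expect_true(tab$ci_low[2] < 0.4 && 0.4 < tab$ci_high[2])
})

test_that("income trend test scores informative categories and validates input", {
  coh <- make_small_cohort(500, seed = 71)
  tr <- linear_trend_test(coh, model_spec(3, "female"), "income")
  row <- dplyr::filter(tidy(tr), term == "income_score")
  expect_equal(nrow(row), 1)
  expect_true(is.finite(row$p_value))
  # non-informative income levels retained as adjustment dummies
  expect_true(any(grepl("income_noninformative", tidy(tr)$term)))

  coh2 <- make_small_cohort(60, seed = 72)
  coh2$income <- "lt_18k"
  expect_error(linear_trend_test(coh2, model_spec(3, "pooled"), "income"),
               class = "foveapit_validation_error")
})

test_that("the analysis suite produces the published table layout", {
  coh <- generate_cohort(400, seed = 81)
  # ensure every ethnicity and centre level is observed in both strata, as at
  # cohort scale, so realized dummy structures are comparable
  eth <- foveapit:::covariate_levels$ethnicity
  ctr <- foveapit:::covariate_levels$centre
  for (s in c("female", "male")) {
    idx <- which(coh$sex == s & !coh$amd & !coh$diabetic_retinopathy &
                   !coh$macular_disease & !coh$cataract_surgery &
                   !coh$refractive_surgery & !coh$corneal_graft)
    coh$ethnicity[idx[seq_along(eth)]] <- eth
    coh$centre[idx[20 + seq_along(ctr)]] <- ctr
  }
  res <- run_analysis_suite(coh, models = 1:2, sensitivity = TRUE,
                            trend = FALSE)
  expect_s3_class(res$tables, "tbl_df")
  # female and male tables share an identical term structure
  t_f <- dplyr::filter(res$tables, analysis == "m1_female", !sensitivity)
  t_m <- dplyr::filter(res$tables, analysis == "m1_male", !sensitivity)
  expect_identical(t_f$term, t_m$term)
  # crude and adjusted pooled sex differences present, both modes
  expect_equal(nrow(res$sex_difference), 4)
  expect_setequal(unique(res$sex_difference$adjustment), c("crude", "adjusted"))
  # sensitivity refits produced
  expect_true(any(res$tables$sensitivity))
  expect_equal(nrow(res$exclusions), 6)
})

test_that("tidiers and plots expose the fit in broom/ggplot idiom", {
  coh <- make_small_cohort(150, seed = 91)
  fit <- fit_multilevel(coh, model_spec(1, "female"))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "ci_low", "ci_high", "p_value",
                    "df") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_lte(gl$n_eyes, 2 * gl$n_persons)
  expect_s3_class(autoplot(fit), "ggplot")
})
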