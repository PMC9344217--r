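#' Apply the cohort exclusion filters
#'
#' Removes eyes of participants with self-reported age-related macular
#' degeneration, diabetic retinopathy or macular disease, and eyes with
#' cataract, refractive or corneal-graft surgery. In sensitivity mode it
#' additionally drops eyes with spherical equivalent below -6 D or above +6 D
#' and visual acuity below 80 ETDRS letters.
#'
#' @param cohort Eye-level cohort tibble (see [generate_cohort()]).
#' @param sensitivity Apply the refractive/acuity sensitivity exclusions too?
#' @return A list: `cohort` (the retained eyes) and `tally`, a tibble of
#'   `(reason, n_excluded)` in application order.
#' @export
apply_exclusions <- function(cohort, sensitivity = FALSE) {
  steps <- list(
    "age-related macular degeneration" = function(d) d$amd,
    "diabetic retinopathy" = function(d) d$diabetic_retinopathy,
    "macular disease" = function(d) d$macular_disease,
    "cataract surgery" = function(d) d$cataract_surgery,
    "refractive surgery" = function(d) d$refractive_surgery,
    "corneal graft surgery" = function(d) d$corneal_graft)
  if (sensitivity) {
    steps <- c(steps, list(
      "spherical equivalent < -6 D or > 6 D" = function(d) d$se < -6 | d$se > 6,
      "visual acuity < 80 ETDRS letters" = function(d) d$va < 80))
  }
  tally <- tibble::tibble(reason = names(steps), n_excluded = 0L)
  d <- cohort
  for (i in seq_along(steps)) {
    drop <- steps[[i]](d)
    drop[is.na(drop)] <- FALSE
    tally$n_excluded[i] <- sum(drop)
    d <- d[!drop, , drop = FALSE]
  }
  list(cohort = d, tally = tally)
}

#' Standardize foveal curvature to z-scores
#'
#' `(x - mean(x)) / sd(x)` over the full included analysis sample (both sexes
#' pooled), so model coefficients read as SD changes in foveal curvature.
#'
#' @param values Numeric vector (>= 2 values, positive SD).
#' @return Standardized values (mean 0, sample SD 1).
#' @export
zscore_fc <- function(values) {
  if (length(values) < 2 || anyNA(values))
    stop_qc("need >= 2 non-missing values to standardize.",
            "foveapit_validation_error")
  s <- sd(values)
  if (s == 0) stop_qc("cannot z-score a constant vector.",
                      "foveapit_validation_error")
  (values - mean(values)) / s
}

#' Specify one of the nested multilevel models
#'
#' Model 1 adjusts for age (per decade), ethnicity, height (per 5 cm) and
#' assessment centre; model 2 adds visual acuity (per 5 letters), spherical
#' equivalent and corneal astigmatism (per diopter), intraocular pressure,
#' macular curvature (per 0.01) and center point retinal thickness (per
#' 10 um); model 3 adds deprivation quintile, education, fluid intelligence,
#' annual income and birth order. Fixed effects are nested by construction
#' (model 2 contains model 1's, model 3 contains model 2's). Analyses are
#' sex-stratified; `stratum = "pooled"` adds a sex term instead, for the
#' crude/adjusted sex-difference estimates.
#'
#' @param model 1, 2 or 3.
#' @param stratum `"female"`, `"male"` or `"pooled"`.
#' @param outcome `"fc_z"` (default) or `"fc_raw_x100"`.
#' @return A list of class `model_spec` with the ordered fixed-effect terms.
#' @export
model_spec <- function(model = 1L, stratum = c("female", "male", "pooled"),
                       outcome = c("fc_z", "fc_raw_x100")) {
  stopifnot(model %in% 1:3)
  stratum <- match.arg(stratum)
  outcome <- match.arg(outcome)
  terms <- c("age_decade", "ethnicity", "height_5cm", "centre")
  if (model >= 2) terms <- c(terms, "va_5", "se", "astig", "iop", "mc_001", "cprt_10")
  if (model >= 3) terms <- c(terms, "townsend", "education",
                             "fluid_intelligence", "income", "birth_order")
  if (stratum == "pooled") terms <- c("sex", terms)
  structure(list(model_id = as.integer(model), stratum = stratum,
                 outcome = outcome, fixed_effects = terms,
                 random_effects = "(1 | person_id)"),
            class = "model_spec")
}

# Categorical code lists with reference level first and an explicit
# "missing" level (kept, not dropped, to minimize data loss).
covariate_levels <- list(
  sex = c("female", "male"),
  ethnicity = c("white", "black", "asian", "other", "mixed", "chinese",
                "prefer_not_to_say", "missing"),
  centre = paste0("centre_", 1:6),
  townsend = c("1", "2", "3", "4", "5", "missing"),
  education = c("degree", "o_levels", "a_levels", "none", "missing"),
  income = c("lt_18k", "18_31k", "31_52k", "52_100k", "gt_100k",
             "prefer_not_to_say", "missing"),
  birth_order = c("1", "2", "3", "4", "missing"))

#' Encode covariates for model fitting
#'
#' Rescales continuous covariates to their conventional reporting increments
#' (age/10, height/5, VA/5, CPRT/10; macular curvature is already "per 0.01"
#' on its x100 scale), dummy-codes categoricals against the published
#' reference levels (white ethnicity, lowest income band, birth order 1), and
#' keeps "missing" as an explicit level. Rows missing a *continuous* model
#' covariate (fluid intelligence) are dropped. Factor terms left with fewer
#' than two observed levels are removed from the term list.
#'
#' @param data Eye-level cohort data (post-exclusion, with the outcome).
#' @param spec A [model_spec()].
#' @return A list: `data` (encoded model frame) and `terms` (the retained
#'   fixed-effect terms).
#' @export
encode_covariates <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  d <- dplyr::mutate(data,
    age_decade = .data$age / 10,
    height_5cm = .data$height / 5,
    va_5 = if ("va" %in% names(data)) .data$va / 5 else NULL,
    mc_001 = if ("mc_x100" %in% names(data)) .data$mc_x100 else NULL,
    cprt_10 = if ("cprt_um" %in% names(data)) .data$cprt_um / 10 else NULL)
  for (nm in intersect(names(covariate_levels), names(d))) {
    known <- unique(as.character(d[[nm]]))
    bad <- setdiff(known[!is.na(known)], covariate_levels[[nm]])
    if (length(bad))
      stop_qc(paste0("unknown ", nm, " code(s): ", paste(bad, collapse = ", ")),
              "foveapit_validation_error")
    d[[nm]] <- factor(as.character(d[[nm]]), levels = covariate_levels[[nm]])
  }
  terms <- spec$fixed_effects
  missing_cols <- setdiff(terms, names(d))
  if (length(missing_cols))
    stop_qc(paste0("covariates absent from data: ",
                   paste(missing_cols, collapse = ", ")),
            "foveapit_validation_error")
  keep <- stats::complete.cases(d[, terms, drop = FALSE])
  d <- d[keep, , drop = FALSE]
  d <- droplevels(d)
  degenerate <- vapply(terms, function(t) is.factor(d[[t]]) &&
                         nlevels(d[[t]]) < 2L, logical(1))
  list(data = d, terms = terms[!degenerate])
}

#' Fit a sex-stratified multilevel model of foveal curvature
#'
#' Restricted-maximum-likelihood linear mixed model of the standardized
#' outcome on the model's fixed effects with a person-level random intercept,
#' so both eyes of a participant contribute. Per-term Wald t-tests use the
#' Satterthwaite degrees-of-freedom approximation; coefficients read as SD
#' change in foveal curvature per stated covariate increment.
#'
#' @param data Eye-level data containing the outcome column (`fc_z` unless
#'   the model spec says otherwise), `person_id`, and the model covariates.
#' @param spec A [model_spec()]. Rows are subset to its stratum unless pooled.
#' @return An object of class `fovea_fit`; see [tidy.fovea_fit()] and
#'   [glance.fovea_fit()]. Contains the coefficient table (`coefs`), variance
#'   components, sizes, convergence/singularity flags and the underlying
#'   `merMod` fit.
#' @export
fit_multilevel <- function(data, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$stratum != "pooled") data <- data[data$sex == spec$stratum, , drop = FALSE]
  if (!nrow(data))
    stop_qc("stratum subset is empty.", "foveapit_validation_error")
  if (!spec$outcome %in% names(data))
    stop_qc(paste0("outcome column `", spec$outcome, "` not found; ",
                   "z-score the cohort first (see zscore_fc())."),
            "foveapit_validation_error")
  enc <- encode_covariates(data, spec)
  fml <- stats::as.formula(paste(
    spec$outcome, "~", paste(enc$terms, collapse = " + "), "+ (1 | person_id)"))
  fit <- suppressMessages(lme4::lmer(fml, data = enc$data, REML = TRUE))
  vc <- lme4::VarCorr(fit)
  singular <- lme4::isSingular(fit)
  conv <- length(fit@optinfo$conv$lme4) == 0L
  coefs <- satterthwaite_coefs(fit)
  structure(list(
    spec = spec, formula = fml, coefs = coefs,
    sd_person = attr(vc$person_id, "stddev")[[1]],
    sd_residual = stats::sigma(fit),
    n_eyes = nrow(enc$data),
    n_persons = length(unique(enc$data$person_id)),
    converged = conv, singular = singular, fit = fit
  ), class = "fovea_fit")
}

#' @export
print.fovea_fit <- function(x, ...) {
  cat(sprintf("<fovea_fit> model %d, %s stratum: %d eyes of %d persons\n",
              x$spec$model_id, x$spec$stratum, x$n_eyes, x$n_persons))
  cat(sprintf("  person SD %.3f, residual SD %.3f%s\n", x$sd_person,
              x$sd_residual,
              if (x$singular) " (singular)" else if (!x$converged) " (non-convergence)" else ""))
  print(x$coefs, n = Inf)
  invisible(x)
}

#' Linear trend test over an ordinal covariate
#'
#' Refits the model with the ordinal covariate entered as a single
#' integer-scored term (categories scored 1..K). Non-informative levels
#' ("prefer not to say", "missing") are excluded from the scoring but kept in
#' the model as adjustment dummies.
#'
#' @param data Eye-level data (as for [fit_multilevel()]).
#' @param spec A [model_spec()] whose fixed effects include the covariate.
#' @param covariate Ordinal covariate name; currently `"income"`.
#' @return A `fovea_fit`; the trend term is named `<covariate>_score`.
#' @export
linear_trend_test <- function(data, spec = model_spec(3), covariate = "income") {
  stopifnot(covariate %in% spec$fixed_effects)
  if (spec$stratum != "pooled") data <- data[data$sex == spec$stratum, , drop = FALSE]
  score <- switch(covariate,
    income = income_score(as.character(data[[covariate]])),
    stop_qc(paste0("no ordinal scoring defined for `", covariate, "`."),
            "foveapit_validation_error"))
  informative <- sort(unique(score[!is.na(score)]))
  if (length(informative) < 3L)
    stop_qc("fewer than 3 informative ordinal levels.",
            "foveapit_validation_error")
  sc_name <- paste0(covariate, "_score")
  data[[sc_name]] <- ifelse(is.na(score), 0, score)
  # retain non-informative levels as dummies only
  ni <- is.na(score)
  data[[paste0(covariate, "_noninformative")]] <-
    ifelse(ni, as.character(data[[covariate]]), "scored")
  spec2 <- spec
  spec2$fixed_effects[spec$fixed_effects == covariate] <- sc_name
  if (any(ni)) spec2$fixed_effects <- c(spec2$fixed_effects,
                                        paste0(covariate, "_noninformative"))
  spec2$stratum <- "pooled" # already subset above; avoid double filtering
  fit <- fit_multilevel(data, spec2)
  fit$spec <- spec
  fit$trend_term <- sc_name
  fit
}

#' Run the full sex-stratified association analysis
#'
#' Applies the exclusion filters, z-scores foveal curvature on the pooled
#' included sample, and fits models 1-3 in each sex stratum, the income
#' linear-trend refit (model 3), and the pooled crude and model-1-adjusted
#' sex difference. Optionally repeats everything on the sensitivity-filtered
#' cohort (extreme refraction / low acuity removed).
#'
#' @param cohort Eye-level cohort (see [generate_cohort()] for the layout).
#' @param models Which of models 1-3 to fit.
#' @param sensitivity Also run the sensitivity re-fits?
#' @param trend Include the income linear-trend refit (needs model 3)?
#' @param outcome_column Raw outcome column to standardize (`fc_raw`).
#' @return An object of class `fovea_analysis`: `tables` (one tidy coefficient
#'   table; columns `model`, `stratum`, `sensitivity`, term statistics),
#'   `sex_difference` (crude and adjusted), `exclusions` (tally), and `fits`.
#' @export
run_analysis_suite <- function(cohort, models = 1:3, sensitivity = TRUE,
                               trend = TRUE, outcome_column = "fc_raw") {
  run_one <- function(sens) {
    excl <- apply_exclusions(cohort, sensitivity = sens)
    d <- excl$cohort
    d$fc_z <- zscore_fc(d[[outcome_column]])
    fits <- list()
    for (st in c("female", "male")) {
      for (m in models) {
        fits[[paste0("m", m, "_", st)]] <- fit_multilevel(d, model_spec(m, st))
      }
      if (trend && 3L %in% models)
        fits[[paste0("trend_income_", st)]] <-
          linear_trend_test(d, model_spec(3, st), "income")
    }
    sex_fits <- list(
      crude = fit_multilevel(d, sex_difference_spec(crude = TRUE)),
      adjusted = fit_multilevel(d, model_spec(1, "pooled")))
    list(fits = fits, sex_fits = sex_fits, tally = excl$tally)
  }
  runs <- list(main = run_one(FALSE))
  if (sensitivity) runs$sensitivity <- run_one(TRUE)

  tables <- purrr::map_dfr(names(runs), function(rn) {
    purrr::map_dfr(names(runs[[rn]]$fits), function(fn) {
      dplyr::mutate(tidy(runs[[rn]]$fits[[fn]]),
                    analysis = fn, sensitivity = rn == "sensitivity",
                    .before = 1)
    })
  })
  sex_difference <- purrr::map_dfr(names(runs), function(rn) {
    purrr::map_dfr(c("crude", "adjusted"), function(kind) {
      f <- runs[[rn]]$sex_fits[[kind]]
      dplyr::mutate(
        dplyr::filter(tidy(f), .data$term == "sexmale"),
        adjustment = kind, sensitivity = rn == "sensitivity", .before = 1)
    })
  })
  structure(list(tables = tables, sex_difference = sex_difference,
                 exclusions = runs$main$tally,
                 fits = purrr::map(runs, "fits")),
            class = "fovea_analysis")
}

# Pooled model with sex as the only fixed effect (crude sex difference).
sex_difference_spec <- function(crude = TRUE) {
  s <- model_spec(1, "pooled")
  if (crude) s$fixed_effects <- "sex"
  s
}

#' @export
print.fovea_analysis <- function(x, ...) {
  cat("<fovea_analysis>\n")
  cat("  exclusion tally:\n")
  print(x$exclusions)
  cat("  sex difference (SD units):\n")
  print(dplyr::select(x$sex_difference, "adjustment", "sensitivity",
                      "estimate", "ci_low", "ci_high", "p_value"))
  cat("  coefficient tables: ", nrow(x$tables), " rows across ",
      length(unique(x$tables$analysis)), " fits\n", sep = "")
  invisible(x)
}
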