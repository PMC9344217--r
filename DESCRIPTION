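Package: foveapit
Title: Foveal Pit Morphometry from OCT Volumes with Multilevel Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies foveal morphology from macular optical coherence
    tomography (OCT) volume scans and relates it to cohort covariates. Retinal
    boundaries (internal limiting membrane and retinal pigment epithelium) are
    segmented per B-scan by an A* shortest-path search on gradient cost images;
    foveal curvature is the leading coefficient of a quadratic fitted to the ILM
    around the thinnest-retina center, macular curvature the median quadratic
    leading coefficient of the RPE over the 32 central B-scans, and center point
    retinal thickness the ILM-to-RPE distance at the fovea center. A synthetic
    OCT volume generator with known ground-truth boundaries and a two-eyes-per-
    person synthetic cohort generator support end-to-end testing; sex-stratified
    linear mixed models (restricted maximum likelihood, person-level random
    intercepts, Satterthwaite degrees of freedom) estimate standardized
    covariate associations with foveal curvature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
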