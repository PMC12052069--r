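Package: twophasesurv
Title: Two-Phase Sampling Designs and Estimators for Time-to-Event Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for two-phase (phase 1: cheap
    covariates on a full cohort; phase 2: expensive covariates on a selected
    subset) studies of time-to-event outcomes. Implements case-cohort,
    stratified case-cohort, stratified extreme case-control, and optimal
    martingale-residual phase-2 sampling designs; design-weighted Cox and
    logistic estimators; a semiparametric maximum-likelihood EM estimator that
    treats the expensive covariate as missing for unselected subjects with a
    nonparametric conditional covariate distribution (Cox and logistic outcome
    models); and a replicate-level evaluation harness tabulating type I error,
    power, relative bias, and relative RMSE across designs and methods on
    Weibull proportional-hazards cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
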