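Package: tacrodose
Title: Tacrolimus Trough Forecasting and Dose Suggestion After Liver
    Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, prediction and dose-advisory tools for tacrolimus
    therapeutic drug monitoring in the first two weeks after liver
    transplantation. Provides a synthetic pharmacokinetic cohort generator
    with clinician-style titration toward an 8-10 ng/mL trough target, a
    one-compartment first-order-absorption population-PK comparator with
    piecewise covariate-dependent clearance and volume, supervised window
    construction with multiple imputation and zero substitution, four
    next-day trough predictors (a recurrent sequence model, gradient-boosted
    regression trees, linear regression and the population-PK model), a
    resampling evaluation harness reporting RMSE, MAE, MDPE and MDAPE, and a
    dose advisor that sweeps candidate doses, builds 3x3 dose-by-concentration
    contingency tables and computes clinical outcome flags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
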