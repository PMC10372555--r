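Package: mortsae
Title: Small-Area Estimation of Crisis-Attributable Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate total, counterfactual and excess mortality
    (all-age and under-5) by district and month in humanitarian crises, from
    retrospective household mortality surveys, reconstructed population
    denominators and lagged district-month predictor series. Implements
    SMART-style survey reanalysis with midpoint person-time accounting,
    graded multi-source population denominator reconstruction with
    displacement adjustment, predictor preparation (imputation, smoothing,
    lags, categorical banding, per-capita rates, recall-period averaging),
    weighted quasi-Poisson offset regression with an optional district
    random intercept and a predictive selection procedure scored by the
    Dawid-Sebastiani rule on district-level cross-validation, a
    counterfactual scenario engine with a parametric lognormal bootstrap of
    death tolls, bias sensitivity analyses, and a seeded synthetic crisis
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmmTMB
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
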