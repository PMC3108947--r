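Package: cchpredict
Title: Case-Cohort Risk Prediction with Weighted Cox Models and
    Censoring-Adjusted Discrimination Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the incremental predictive value of
    biomarker panels in stratified case-cohort studies. Provides a seeded
    synthetic-cohort generator with log-normal correlated biomarkers and
    Weibull proportional-hazards endpoints, stratified subcohort sampling
    with survey- and sex-specific design weights (Prentice and Barlow
    schemes), a weighted Cox proportional-hazards fitter with robust
    sandwich variance and Breslow baseline hazard, 10-year absolute risk
    prediction, censoring-adjusted discrimination measures (time-horizon
    AUC via inverse-probability-of-censoring weighting, delta-AUC,
    integrated discrimination improvement, category-based net
    reclassification index, pseudo-AIC differences), and design-aware
    stratified bootstrap percentile confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
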