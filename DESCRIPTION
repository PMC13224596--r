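Package: dietkidney
Title: Dietary Patterns and Kidney Function: DASH Scoring, Reduced-Rank
    Regression Patterns and eGFR Association Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving dietary patterns from food frequency
    questionnaire (FFQ) data and relating them to creatinine-based
    estimated glomerular filtration rate (eGFR). Implements DASH
    adherence scoring with sex-specific quantile ranks, reduced-rank
    regression (RRR) extraction of biomarker-driven dietary patterns
    with assay quantile normalization and household-clustered mediator
    adjustment, the race-free CKD-EPI 2021 creatinine equation,
    nutrient-residual energy adjustment, exclusion cascades for
    implausible dietary reports, and sex- and menstrual-status
    stratified linear and penalized-spline association models. A seeded
    synthetic cohort generator with planted pattern directions and
    effect sizes makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
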