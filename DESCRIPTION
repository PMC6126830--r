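Package: psccal
Title: Two-Stage Propensity-Score Calibration for Matched Claims Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrospective matched-cohort studies built from
    longitudinal insurance-claims data when key confounders (smoking,
    alcohol use, body-mass index) are missing from the main database but
    observed in a small external validation survey. Provides a synthetic
    claims-data generator with known ground truth, cohort construction
    (inclusion criteria, Charlson comorbidity index, ratio age-sex
    matching, follow-up derivation), incidence and Cox proportional-hazards
    estimation with propensity-score adjustment, a two-stage
    propensity-score-calibration (regression calibration) correction of
    the exposure log-hazard, percentile-bootstrap confidence intervals
    with follow-up sensitivity analysis, and medication-class exposure
    classification with multivariable Cox modelling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
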