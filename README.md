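# psccal

Two-stage propensity-score calibration for matched insurance-claims
cohorts.

## The problem

Claims databases are large enough to study whether treated chronic
obstructive pulmonary disease (COPD) raises the hazard of prostate
cancer in men over 50, but they record no smoking, alcohol use or
body-mass index — confounders that plausibly drive both the exposure
and the outcome. A small health-interview survey from the same
population does observe them. `psccal` implements the resulting
two-database analysis: build a matched retrospective cohort from claims
tables, estimate crude and propensity-adjusted hazard ratios with Cox
models, and correct the exposure effect for the missing confounders by
propensity-score calibration against the survey, with
percentile-bootstrap confidence intervals.

With `D` the exposure indicator, `E` the shared covariates (age band,
Charlson comorbidity index) and `M` the survey-only confounders, the
main-study model is

    H(t | D, PS) = H0(t) exp(beta D + beta_c PS),      PS = Pr(D = 1 | E)

and the validation survey supplies the least-squares measurement-error
model

    E(PS_m | D, PS_c) = gamma0 + gamma D + gamma_c PS_c

linking the gold-standard score `PS_m = Pr(D = 1 | E, M)` to the
error-prone score `PS_c = Pr(D = 1 | E)`. The calibrated exposure
log-hazard is

    beta* = beta - (beta_c / gamma_c) gamma,       HR* = exp(beta*)

(regression-calibration algebra; a `paper_literal` mode with the
multiplicative form `beta - beta_c gamma_c gamma` is kept for fidelity
audits). Confidence intervals come from a percentile bootstrap that
resamples the cohort and the survey independently (default B = 1000,
interval = order statistics 25 and 975, empirical p floored at 1/B).

Because the study's real databases are access-restricted, the package
includes a synthetic claims generator with known ground truth whose
defaults reproduce the published design (cohort of ~12,800 exposed men
matched 3:1, control incidence near 361 per 100,000 person-years,
survey of 312 + 804 subjects with the published smoking/alcohol/BMI
contrasts), so every estimator is testable for parameter recovery.

## Worked example

```r
library(psccal)

cfg    <- sim_config(n_persons = 30000, seed = 7)
bundle <- simulate_population(cfg)
cohort <- build_cohort(bundle, ratio = 3, seed = 7)

models <- fit_cohort_models(cohort)              # PS + crude + adjusted Cox
val    <- export_validation_sample(bundle, seed = 7)
res    <- run_two_stage(cohort, val, B = 200, seed = 7)
print(res)
```

which prints (exact numbers for this seed):

```
Two-stage propensity-score calibration (standard_rc)
  beta_hat = 0.5853, beta_c_hat = 0.0419
  gamma0 = 0.0006, gamma = 0.0235, gamma_c = 0.9743
  beta_star = 0.5843  (HR* = 1.794)
  bootstrap 95% CI for HR*: 1.332-2.390 (empirical p = 0.005)
```

Reading it: the propensity-adjusted exposure log-hazard in the main
cohort is `beta_hat = 0.585` (HR 1.80, 272 events among 16,400
subjects; the incidences are 633 vs 352 per 100,000 person-years). In
the survey, the gold-standard score differs from the error-prone score
by `gamma = 0.024` between exposure groups at fixed `PS_c`, so the
calibration subtracts `(beta_c/gamma_c) * gamma` — here a small
correction because at this scale the simulated lifestyle confounding is
mild — giving a calibrated hazard ratio of 1.79 with bootstrap 95% CI
1.33–2.39. At the full study scale (`sim_config()` defaults,
n = 93,000) the three estimates order as published: crude > adjusted >
calibrated, with the calibrated estimate closest to the generator's
true conditional hazard ratio of 1.62.

The same objects feed the rest of the pipeline:
`sensitivity_by_followup()` truncates follow-up at 1/2/3 years and
re-estimates, `classify_medication_exposure()` +
`fit_medication_cox()` fit the inhaled-class and co-medication model
within the exposed cohort, `build_table2()` and `hazard_curves()`
assemble the summary table and cumulative-hazard export, and
`psc_parameter_recovery()` runs the bias-removal experiment
(200 replicates at n = 20,000: the uncorrected estimate averages ~0.15
above the true log-hazard 0.48, the calibrated one is unbiased to
within ~0.01).

## Package layout

- `R/synthetic_data.R` — claims-population generator, validation-survey
  export, ground-truth cohort shortcut
- `R/cohort_builder.R` — entry criteria, Charlson index, 3:1 matching,
  follow-up
- `R/outcome_models.R` — incidence, propensity scores, Cox fits
- `R/psc_calibration.R` — measurement-error model and the calibration
  estimator
- `R/bootstrap.R` — percentile bootstrap, follow-up sensitivity
- `R/medication.R` — exposure classification and the medication Cox
  model
- `R/reporting.R` — chi-square utility, summary tables, hazard curves
- `vignettes/two-stage-calibration.Rmd` — model, assumptions, generator
  calibration, numerical choices, limitations
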