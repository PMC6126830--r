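---
title: "Two-stage propensity-score calibration for matched claims cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage propensity-score calibration for matched claims cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(psccal)
```

## The problem

Insurance-claims databases record diagnoses, prescriptions and
demographics for very large populations, which makes them attractive for
studying whether a chronic exposure — here, treated chronic obstructive
pulmonary disease (COPD) in men over 50 — raises the hazard of a later
outcome (prostate cancer).  What claims databases do not record are
lifestyle confounders: smoking, alcohol use and body-mass index all
plausibly affect both the odds of being a treated COPD patient and the
outcome hazard.  A separate, much smaller health-interview survey drawn
from the same underlying population does observe those variables,
alongside the covariates the claims data share (age, comorbidity
burden).

`psccal` implements the resulting two-database analysis end to end:

1. build a matched retrospective cohort from claims tables
   (`identify_copd_cohort()`, `match_controls()`, `compute_followup()`);
2. estimate crude and propensity-adjusted hazard ratios
   (`fit_propensity()`, `fit_cox()`);
3. correct the exposure log-hazard for the confounders missing from the
   main database using the validation survey (`run_two_stage()`);
4. attach percentile-bootstrap intervals (`percentile_bootstrap()`) and
   follow-up sensitivity analyses (`sensitivity_by_followup()`);
5. analyse medication-class effects within the exposed cohort
   (`classify_medication_exposure()`, `fit_medication_cox()`).

Because the real databases are access-restricted, the package ships a
synthetic claims generator (`simulate_population()`) whose defaults
emulate the published study design and which retains ground truth, so
every estimator can be tested for parameter recovery.

## The calibration estimator

Write `D` for the exposure indicator, `E` for the shared covariates
(age band and Charlson comorbidity index, the cohort being all male),
and `M` for the confounders observed only in the validation survey.
Three propensity scores appear:

* `PS = Pr(D = 1 | E)` in the main cohort;
* `PS_c = Pr(D = 1 | E)` refitted within the validation sample (the
  *error-prone* score);
* `PS_m = Pr(D = 1 | E, M)` in the validation sample (the *gold
  standard*).

The main-study outcome model is the proportional-hazards fit

`H(t | D, PS) = H0(t) exp(beta * D + beta_c * PS)`,

estimated by partial likelihood (Efron ties, convergence tolerance
1e-10 so coefficients reproduce to at least six digits).  The
validation sample supplies a least-squares measurement-error model

`E(PS_m | D, PS_c) = gamma0 + gamma * D + gamma_c * PS_c`.

Substituting that conditional expectation into the gold-standard hazard
model `exp(beta_true * D + beta_m * PS_m)` gives
`beta = beta_true + beta_m * gamma` and `beta_c = beta_m * gamma_c`,
so the calibrated exposure log-hazard is

`beta_star = beta - (beta_c / gamma_c) * gamma`,

with `exp(beta_star)` the calibrated hazard ratio.  This is classical
regression-calibration algebra; the package also provides a
`paper_literal` mode, `beta_star = beta - beta_c * gamma_c * gamma`,
because the multiplicative form appears in print in this literature.
The two agree when `gamma = 0` (no differential missingness) or
`|gamma_c| = 1`, and the division form is the default because only it
satisfies the invariances one should demand of the estimator: if
`PS_m` equals `PS_c` the correction vanishes identically, and the
result is unchanged under an affine rescaling of the error-prone score
applied consistently to both fits.  When `|gamma_c|` falls below 1e-6
the correction is unidentified and `calibrate()` aborts rather than
dividing by noise.

Confidence intervals for `beta_star` come from a percentile bootstrap
(default B = 1000) that resamples the main cohort and the validation
sample independently, each within itself; the interval is the pair of
order statistics at ranks `ceiling(0.025 B)` and `floor(0.975 B)` (25
and 975 at B = 1000).  The empirical p-value for a null log-hazard of
zero is the sign-based two-sided proportion
`2 min(#{b* <= 0}, #{b* >= 0}) / B`, floored at `1/B` — so 0.001 is the
smallest attainable value at B = 1000; an add-one variant
`(count + 1)/(B + 1)` is available behind a flag.  Replicate `j`
depends only on `(seed, j)`, so results do not depend on evaluation
order.

### When the correction works — and when it does not

The estimator assumes *surrogacy*: given the exposure and the
gold-standard score, the error-prone score must carry no further
outcome information.  In structural terms, surrogacy holds when each
covariate's effect on the outcome log-hazard is proportional to its
effect on the exposure log-odds, so that iso-`PS_m` contours are also
iso-hazard contours.  Notably, a binary confounder with odds ratio 2 on
exposure and hazard ratio 1.5 on the outcome satisfies this exactly
(`log(1.5)/log(2)` is the shared proportionality factor).

When surrogacy fails the correction can be substantially incomplete or
excessive, and we document both regimes because the package's own
experiments exhibit them:

* with shared covariates that influence the outcome with weights *not*
  proportional to their exposure log-odds, and probability-scale scores
  spanning a wide range, the linear measurement-error model captures
  only part of the confounding and `beta_star` removes roughly half of
  the bias;
* with shared covariates nearly unrelated to exposure, `gamma_c` tends
  to zero and the division inflates the correction.

The parameter-recovery experiment shipped with the package
(`psc_parameter_recovery()`, configuration in `recovery_config()`)
therefore evaluates the estimator in the regime it is designed for:
smoking and alcohol each double the exposure odds and multiply the
outcome hazard by 1.5, BMI plays a weak negative role, the band-level
age effect on the outcome is proportional to its exposure log-odds,
comorbidities are balanced, and the true conditional exposure
log-hazard is 0.48.  Across 200 replicates of n = 20,000 the
uncorrected propensity-adjusted estimate averages about +0.15 above the
truth while the calibrated estimate is unbiased to within about 0.01;
the absolute-error comparison and the bias bound are asserted by the
test suite and recomputed by `scripts/acceptance.R`.  Outside the
surrogate regime the method's incomplete correction is a genuine
limitation of propensity-score calibration, not of this implementation.

## The synthetic claims generator

`sim_config()` parameterizes a male claims population over 50.  The
defaults encode the published study's design, chosen once, analytically,
from its printed summary tables:

* **Scale and matching.** `n_persons = 93,000` yields roughly 12,800
  treated COPD cases after the entry criteria, matched 3:1 on sex and
  age band; the published cohort was 12,774 / 38,322.
* **Age structure.** Three bands (51–60, 61–70, >70) with population
  shares 0.35 / 0.30 / 0.35 and exposure log-odds offsets 0 / 0.45 /
  1.30, which reproduce the published case age distribution
  (18.5 / 24.0 / 57.5 per cent) while leaving at least three matchable
  controls per case in every band.
* **Outcome rates.** Baseline hazard 0.0030 events per person-year at
  reference covariates and an exponential withdrawal/death clock at
  0.055 per year: together with administrative censoring at the end of
  2008 these imply a mean follow-up near 4.0 years and a control
  incidence near 361 per 100,000 person-years, the published rate; the
  true conditional exposure log-hazard defaults to `log(1.62)`, the
  published calibrated estimate.
* **Lifestyle confounders.** Marginal smoking prevalence 0.512, alcohol
  0.389, BMI Normal(24.1, 3.8) truncated to [14, 45]; their exposure
  log-odds (0.34, −0.20, −0.055 per BMI unit) are back-derived from the
  published survey contrasts (smoking 59.6 vs 51.2 per cent, alcohol
  34.3 vs 38.9, BMI 23.4 vs 24.2).  Their outcome effects (hazard
  ratios 1.30, 1.10, 1.01 per unit) are not published; we chose modest
  values plausible for prostate-cancer epidemiology, which produce the
  published ordering crude > adjusted > calibrated.
* **Comorbidities.** Fifteen Charlson-listed conditions drawn
  independently, conditional on exposure, at the published group
  prevalences.  The default comorbidity-index weights are unit weights
  (one point per condition), because the published mean scores (1.7
  exposed, 1.2 controls) equal the sums of the published prevalences
  exactly; the classic Charlson weight set is available via
  `cci_weights("charlson")`.
* **Medication.** Treated cases receive an inhaled class (SAMA, SABA,
  LAMA, LABA, LABA+ICS), an oral xanthine ("none" class), or a
  combination (excluded from the medication model), with shares
  0.22/0.22/0.08/0.03/0.18/0.22/0.05; 30 per cent of long-acting users
  also receive short (7-day) rescue claims.  Class hazard effects
  default to the published medication model (1.61, 1.89, 0.94, 0.95,
  0.87) and co-medication effects to statin 0.63, aspirin 0.55, oral
  steroid 0.80, NSAID 1.01; class effects are centred within the
  exposed cohort so the marginal exposure effect stays at its
  configured value while within-cohort contrasts equal the configured
  ratios.
* **Censoring observability.** The persons table carries an
  `exit_date`, as enrollment files do in real claims data; follow-up
  derivation treats it as the death/withdrawal censor date.

Randomness is split into independent streams (ages, confounders,
exposure, comorbidities, medication, event times, censoring, claim
plumbing), each seeded deterministically from the master seed, so a
fixed `(config, seed)` reproduces the bundle byte for byte.

What the generator deliberately does not emulate: correlated
comorbidities, secular trends in diagnosis or prescribing, dose
titration and adherence, code miscoding/noise, and the household
structure of the interview survey.  Passing tests therefore demonstrate
estimator correctness under the assumed data-generating process, not
robustness to real-world coding artefacts.

## Cohort-construction conventions

* "At least two consecutive diagnoses" is implemented as two or more
  COPD diagnosis claims on distinct dates (`min_dx_dates`), the weakest
  defensible reading; the index date is the first qualifying
  pharmacotherapy claim in the 2004 accrual window.
* Ages derive from birth year under a July-1 mid-year convention; entry
  requires age 51 or more at index ("older than 50" read strictly);
  the matching band uses the accrual-year age.
* Matching is without replacement within sex-by-age-band strata using a
  seeded shuffle; within a stratum, cases are processed in index-date
  order, and candidate controls with an outcome diagnosis before the
  case's index date are discarded permanently (safe because rejection
  is monotone in the index date).  Controls inherit their case's index
  date, which avoids immortal-time bias.  Pool exhaustion is a hard
  error naming the stratum and shortfall, never silent partial
  matching.
* Date conventions are half-open: a claim dated on the index date is
  pre-index for comorbidity assessment and post-index for outcomes.
* Follow-up runs to the earliest of outcome diagnosis, exit
  (death/withdrawal) and 2008-12-31; a same-day event is given half a
  day of exposure to keep person-time positive.

## Medication-exposure rules

A claim qualifies only if its own days supplied exceed 14 (strictly);
a person-level accumulation variant is behind the `accumulate` switch
because the prose rule is ambiguous.  A person's class is their unique
qualifying class with at least three qualifying claims inside the first
treatment year ("stationary medication"); long-acting users may hold
sub-threshold short-acting rescue claims without losing their class
(the allowance is deliberately one-directional); two qualifying classes
mean exclusion from the medication model; unmapped drug codes warn and
fall into an `unclassified` bucket rather than disappearing.
Co-medication flags (statin, aspirin, oral steroid, NSAID) require a
single claim before the person's censor date, with no duration
threshold.

## Numerical choices and problem sizes

Cox models default to Efron tie handling (claims dates produce heavy
ties); propensity models are plain maximum-likelihood logistic fits
that abort on non-convergence or boundary scores rather than returning
degenerate values.  "Stratified" adjustment is implemented as the score
entered continuously — required by the calibration algebra — with
baseline-hazard stratification available through the `strata` argument
of `fit_cox()`.

The shipped experiments use the sizes stated throughout this vignette:
the study-scale simulation at n = 93,000, the recovery experiment at
200 replicates of n = 20,000 with a 20 per cent validation fraction,
bootstrap coverage checks at n = 200 with B = 500 over 200 outer
replicates, and B = 200 bootstrap replicates for the study-scale
calibrated interval in the acceptance script (B = 1000 remains the
package default for final analyses).

## Known limitations

* Surrogacy is untestable from the main study alone; the calibrated
  estimate should be reported alongside the uncorrected one, as the
  acceptance script does.
* The bootstrap resamples subjects, not matched sets, by default
  (matched-set resampling would condition on the realized matching);
  the paper-analog behaviour is the subject bootstrap.
* No competing-risk handling: death censors rather than competes.
* The generator's independence assumptions (comorbidities, medication
  assignment) make the medication model's no-confounding recovery test
  easier than real prescribing data would be.
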