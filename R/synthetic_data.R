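# Synthetic claims-data generator.
#
# Emulates the structure of a longitudinal claims database (persons,
# diagnosis claims with ICD-9-CM codes, prescription claims with drug class
# and days supplied) together with an external validation survey in which
# the lifestyle confounders hidden from the claims data (smoking, alcohol,
# BMI) are observed.  Ground truth is retained so that estimator bias can
# be measured directly.

STUDY_START <- as.Date("2004-01-01")

#' Comorbidity prevalence table used by the generator
#'
#' One row per Charlson-listed condition with a representative ICD-9-CM
#' code and its prevalence conditional on COPD status.  Defaults reproduce
#' the condition list and group prevalences of the study's descriptive
#' table (e.g. myocardial infarction 2.3\% vs 1.9\%, congestive heart
#' failure 16.3\% vs 7.8\%, cerebrovascular disease 25.3\% vs 18.3\%).
#'
#' @return data.frame with columns `condition`, `icd9`, `prev_copd`,
#'   `prev_control`.
#' @export
default_comorbidity_table <- function() {
  data.frame(
    condition = c("mi", "chf", "pvd", "cvd", "dementia", "rheumatic",
                  "peptic_ulcer", "mild_liver", "diabetes",
                  "diabetes_complicated", "paraplegia", "renal",
                  "severe_liver", "metastatic_cancer", "aids"),
    icd9 = c("410", "428", "443", "433", "290", "714.0", "531", "571",
             "250.0", "250.4", "344", "585", "572", "196", "042"),
    prev_copd    = c(0.023, 0.163, 0.070, 0.253, 0.078, 0.040, 0.401,
                     0.231, 0.232, 0.067, 0.018, 0.082, 0.004, 0.006, 0.001),
    prev_control = c(0.019, 0.078, 0.050, 0.183, 0.044, 0.024, 0.262,
                     0.168, 0.216, 0.066, 0.013, 0.067, 0.003, 0.006, 0.0002),
    stringsAsFactors = FALSE)
}

#' Weight map for the Charlson comorbidity index
#'
#' `"unit"` (default) scores one point per listed condition, which
#' reproduces the mean index of 1.7 (COPD) / 1.2 (controls) implied by the
#' study's prevalence table.  `"charlson"` applies the classic weights
#' (2 for complicated diabetes, paraplegia/hemiplegia, renal and
#' moderate/severe liver disease; 6 for metastatic carcinoma and AIDS).
#'
#' @param scheme `"unit"` or `"charlson"`.
#' @return named numeric vector of weights keyed by condition.
#' @export
cci_weights <- function(scheme = c("unit", "charlson")) {
  scheme <- match.arg(scheme)
  cond <- default_comorbidity_table()$condition
  w <- setNames(rep(1, length(cond)), cond)
  if (scheme == "charlson") {
    w[c("diabetes_complicated", "paraplegia", "renal", "severe_liver")] <- 2
    w[c("metastatic_cancer", "aids")] <- 6
  }
  w
}

INHALED_CLASSES <- c("SAMA", "SABA", "LAMA", "LABA", "LABA_ICS")
LONG_ACTING <- c("LAMA", "LABA", "LABA_ICS")
COMED_CLASSES <- c("statin", "aspirin", "steroid_oral", "nsaid")

#' Default medication model for the generator
#'
#' Class shares among treated COPD patients, hazard effects of each inhaled
#' class (defaults are the multivariable hazard ratios of the medication
#' analysis: SAMA 1.61, SABA 1.89, LAMA 0.94, LABA 0.95, LABA+ICS 0.87)
#' and of co-medications (statin 0.63, aspirin 0.55, oral steroid 0.80,
#' NSAID 1.01).  Class effects are centred within the COPD cohort so the
#' marginal COPD effect stays at `true_log_hr_copd`.
#'
#' @return list with `class_probs`, `effects`, `rescue_prob`,
#'   `comed_probs`, `comed_effects`.
#' @export
default_medication_config <- function() {
  list(
    class_probs = c(SAMA = 0.22, SABA = 0.22, LAMA = 0.08, LABA = 0.03,
                    LABA_ICS = 0.18, none = 0.22, combination = 0.05),
    effects = c(SAMA = log(1.61), SABA = log(1.89), LAMA = log(0.94),
                LABA = log(0.95), LABA_ICS = log(0.87)),
    rescue_prob = 0.30,
    comed_probs = c(statin = 0.15, aspirin = 0.12, steroid_oral = 0.25,
                    nsaid = 0.10),
    comed_effects = c(statin = log(0.63), aspirin = log(0.55),
                      steroid_oral = log(0.80), nsaid = log(1.01)))
}

#' Simulation configuration
#'
#' Parameterizes the synthetic claims population.  The defaults are
#' calibrated to the study design the package analyses: a male claims
#' population over 50 with an exposed (COPD) fraction whose age structure
#' matches the published cohort (18.5/24.0/57.5\% across bands 51-60 /
#' 61-70 / >70), a true conditional COPD log-hazard of log(1.62), control
#' incidence near 361 per 100,000 person-years, lifestyle-confounder
#' contrasts matching the validation survey (smoking 59.6 vs 51.2\%,
#' alcohol 34.3 vs 38.9\%, BMI 23.4 vs 24.2), comorbidity prevalences from
#' [default_comorbidity_table()], and administrative censoring at the end
#' of 2008 with an annual withdrawal/death rate of 0.055.
#'
#' @param n_persons number of persons to simulate.
#' @param true_log_hr_copd conditional log hazard ratio of COPD on the
#'   outcome given all confounders.
#' @param baseline_hazard outcome events per person-year at reference
#'   covariates (age 65, non-smoker, non-drinker, BMI 24, CCI 0, no COPD).
#' @param log_hr_age outcome log hazard ratio per year of age.
#' @param age_band_log_hr optional named vector of band-level outcome
#'   log hazard ratios (replaces the continuous age effect when given;
#'   used to build designs in which the age effect on the outcome is
#'   proportional to its effect on exposure log-odds).
#' @param age_band_probs population shares of the three age bands.
#' @param copd_intercept baseline log-odds of COPD.
#' @param copd_age_log_odds additive log-odds of COPD per age band.
#' @param confounder_effects list with elements `smoking`, `alcohol`,
#'   `bmi`; each a numeric vector `c(copd_log_odds =, outcome_log_hr =)`.
#'   BMI effects apply per unit, centred at `bmi_ref`.
#' @param smoking_prev,alcohol_prev marginal Bernoulli prevalences of the
#'   lifestyle confounders.
#' @param bmi_mean,bmi_sd,bmi_range,bmi_ref BMI distribution: Normal
#'   truncated to `bmi_range`, effects centred at `bmi_ref`.
#' @param comorbidity_prevalences data.frame as
#'   [default_comorbidity_table()].
#' @param cci_weight_scheme `"unit"` or `"charlson"` (see [cci_weights()]).
#' @param cci_log_hr outcome log hazard ratio per CCI point.
#' @param prior_cancer_prob probability of a pre-study outcome diagnosis
#'   (such persons must be excluded by the cohort builder).
#' @param censoring list with `admin_end` (Date) and `annual_rate`
#'   (exponential withdrawal/death rate per person-year).
#' @param accrual_window Date vector of length 2: window of index
#'   (first-treatment) dates.
#' @param claims_compliance fraction of COPD persons whose claims satisfy
#'   the cohort-entry criteria (two diagnosis dates, three prescription
#'   claims, clean washout year).
#' @param medication list as [default_medication_config()].
#' @param validation list controlling the validation export: either
#'   `fraction` or `n_by_group = c(copd =, control =)` (default 312/804,
#'   the survey sizes of the study).
#' @param claims if FALSE, skip claim-row generation and return only
#'   persons, covariates and ground truth (fast path for estimator
#'   experiments).
#' @param seed integer seed; identical config and seed give identical
#'   output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_persons = 93000,
                       true_log_hr_copd = log(1.62),
                       baseline_hazard = 0.0030,
                       log_hr_age = log(1.02),
                       age_band_log_hr = NULL,
                       age_band_probs = c("51-60" = 0.35, "61-70" = 0.30,
                                          ">70" = 0.35),
                       copd_intercept = -2.5,
                       copd_age_log_odds = c("51-60" = 0, "61-70" = 0.45,
                                             ">70" = 1.30),
                       confounder_effects = list(
                         smoking = c(copd_log_odds = 0.34,
                                     outcome_log_hr = log(1.30)),
                         alcohol = c(copd_log_odds = -0.20,
                                     outcome_log_hr = log(1.10)),
                         bmi     = c(copd_log_odds = -0.055,
                                     outcome_log_hr = 0.010)),
                       smoking_prev = 0.512,
                       alcohol_prev = 0.389,
                       bmi_mean = 24.1, bmi_sd = 3.8,
                       bmi_range = c(14, 45), bmi_ref = 24,
                       comorbidity_prevalences = default_comorbidity_table(),
                       cci_weight_scheme = "unit",
                       cci_log_hr = 0.05,
                       prior_cancer_prob = 0.01,
                       censoring = list(admin_end = as.Date("2008-12-31"),
                                        annual_rate = 0.055),
                       accrual_window = as.Date(c("2004-01-01",
                                                  "2004-12-31")),
                       claims_compliance = 0.9,
                       medication = default_medication_config(),
                       validation = list(n_by_group = c(copd = 312,
                                                        control = 804)),
                       claims = TRUE,
                       seed = 20040101) {
  if (!is.numeric(n_persons) || n_persons < 1)
    stop("configuration error: `n_persons` must be >= 1", call. = FALSE)
  assert_rate(baseline_hazard, "baseline_hazard")
  assert_rate(censoring$annual_rate, "censoring$annual_rate")
  assert_prob(age_band_probs, "age_band_probs")
  if (abs(sum(age_band_probs) - 1) > 1e-8)
    stop("configuration error: `age_band_probs` must sum to 1",
         call. = FALSE)
  assert_prob(smoking_prev, "smoking_prev")
  assert_prob(alcohol_prev, "alcohol_prev")
  assert_prob(claims_compliance, "claims_compliance")
  assert_prob(prior_cancer_prob, "prior_cancer_prob")
  assert_prob(comorbidity_prevalences$prev_copd,
              "comorbidity_prevalences$prev_copd")
  assert_prob(comorbidity_prevalences$prev_control,
              "comorbidity_prevalences$prev_control")
  assert_prob(medication$class_probs, "medication$class_probs")
  assert_prob(medication$comed_probs, "medication$comed_probs")
  if (abs(sum(medication$class_probs) - 1) > 1e-8)
    stop("configuration error: `medication$class_probs` must sum to 1",
         call. = FALSE)
  if (!is.null(validation$fraction))
    assert_prob(validation$fraction, "validation$fraction")
  if (accrual_window[1] >= accrual_window[2])
    stop("configuration error: `accrual_window` start must precede end",
         call. = FALSE)
  structure(list(
    n_persons = as.integer(n_persons),
    true_log_hr_copd = true_log_hr_copd,
    baseline_hazard = baseline_hazard,
    log_hr_age = log_hr_age,
    age_band_log_hr = age_band_log_hr,
    age_band_probs = age_band_probs,
    copd_intercept = copd_intercept,
    copd_age_log_odds = copd_age_log_odds,
    confounder_effects = confounder_effects,
    smoking_prev = smoking_prev,
    alcohol_prev = alcohol_prev,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    bmi_range = bmi_range, bmi_ref = bmi_ref,
    comorbidity_prevalences = comorbidity_prevalences,
    cci_weight_scheme = cci_weight_scheme,
    cci_log_hr = cci_log_hr,
    prior_cancer_prob = prior_cancer_prob,
    censoring = censoring,
    accrual_window = accrual_window,
    claims_compliance = claims_compliance,
    medication = medication,
    validation = validation,
    claims = isTRUE(claims),
    seed = as.integer(seed)),
    class = "sim_config")
}

# Truncated-normal draw by vectorized rejection; n small relative to the
# acceptance region so a handful of passes suffice.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Simulate a claims-style study population
#'
#' Generates persons, diagnosis claims, prescription claims and the hidden
#' ground truth under the confounding structure described in
#' [sim_config()]: lifestyle confounders raise (or lower) both the odds of
#' COPD and the outcome hazard; comorbidities are drawn conditional on
#' COPD status; event times are exponential with log-hazard
#' `log(baseline) + beta * D + confounder terms + age term + CCI term +
#' medication terms`; censoring combines an administrative end date with a
#' competing exponential withdrawal/death clock.  Random draws use
#' independent per-stream seeds so output is reproducible byte-for-byte.
#'
#' @param config a [sim_config()].
#' @return object of class `claims_bundle`: list with `persons`,
#'   `diagnosis_claims`, `prescription_claims` (NULL when
#'   `config$claims = FALSE`), `covariates`, `hidden_truth`, `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_persons
  seed <- config$seed

  # -- persons: age bands, ages, birth years -------------------------------
  ages <- with_seed(stream_seed(seed, 1L), {
    band <- sample(AGE_BANDS, n, replace = TRUE, prob = config$age_band_probs)
    lo <- c("51-60" = 51, "61-70" = 61, ">70" = 71)[band]
    hi <- c("51-60" = 60, "61-70" = 70, ">70" = 85)[band]
    lo + floor(runif(n) * (hi - lo + 1))
  })
  band <- age_band(ages)
  birth_year <- 2004L - as.integer(ages)

  # -- hidden lifestyle confounders ---------------------------------------
  ce <- config$confounder_effects
  M <- with_seed(stream_seed(seed, 2L), {
    data.frame(
      smoking = rbinom(n, 1, config$smoking_prev),
      alcohol = rbinom(n, 1, config$alcohol_prev),
      bmi = round(rnorm_trunc(n, config$bmi_mean, config$bmi_sd,
                              config$bmi_range[1], config$bmi_range[2]), 1))
  })
  bmi_c <- M$bmi - config$bmi_ref

  # -- exposure (COPD) -----------------------------------------------------
  eta <- config$copd_intercept +
    config$copd_age_log_odds[as.character(band)] +
    ce$smoking[["copd_log_odds"]] * M$smoking +
    ce$alcohol[["copd_log_odds"]] * M$alcohol +
    ce$bmi[["copd_log_odds"]] * bmi_c
  copd <- with_seed(stream_seed(seed, 3L), rbinom(n, 1, plogis(eta)))

  # -- comorbidities conditional on exposure ------------------------------
  com <- config$comorbidity_prevalences
  wmap <- cci_weights(config$cci_weight_scheme)
  flags <- with_seed(stream_seed(seed, 4L), {
    out <- lapply(seq_len(nrow(com)), function(i) {
      p <- ifelse(copd == 1, com$prev_copd[i], com$prev_control[i])
      rbinom(n, 1, p)
    })
    names(out) <- com$condition
    as.data.frame(out)
  })
  cci <- as.numeric(as.matrix(flags) %*% wmap[com$condition])

  # -- medication assignment ----------------------------------------------
  med <- config$medication
  med_state <- with_seed(stream_seed(seed, 5L), {
    cls <- rep("none", n)
    cls[copd == 1] <- sample(names(med$class_probs), sum(copd == 1),
                             replace = TRUE, prob = med$class_probs)
    c1 <- sample(INHALED_CLASSES, n, replace = TRUE,
                 prob = med$class_probs[INHALED_CLASSES])
    shift <- sample.int(4L, n, replace = TRUE)
    c2 <- INHALED_CLASSES[((match(c1, INHALED_CLASSES) - 1L + shift) %% 5L) + 1L]
    combo2 <- cbind(c1, c2)
    rescue <- rbinom(n, 1, med$rescue_prob) == 1 & cls %in% LONG_ACTING
    comed <- lapply(COMED_CLASSES,
                    function(m) rbinom(n, 1, med$comed_probs[[m]]))
    names(comed) <- COMED_CLASSES
    c(list(class = cls, rescue = rescue, combo2 = combo2),
      comed)
  })
  inhaled_class <- med_state$class

  # centred class effect keeps the marginal COPD hazard at its target
  eff <- c(med$effects, none = 0, combination = 0)
  centre <- log(sum(med$class_probs * exp(eff[names(med$class_probs)])))
  med_term <- ifelse(copd == 1, eff[inhaled_class] - centre, 0)
  comed_term <- Reduce(`+`, lapply(COMED_CLASSES, function(m)
    med$comed_effects[[m]] * med_state[[m]]))

  # -- event and censoring times (years from study start) -----------------
  loghaz <- log(config$baseline_hazard) +
    config$true_log_hr_copd * copd +
    ce$smoking[["outcome_log_hr"]] * M$smoking +
    ce$alcohol[["outcome_log_hr"]] * M$alcohol +
    ce$bmi[["outcome_log_hr"]] * bmi_c +
    (if (is.null(config$age_band_log_hr))
       config$log_hr_age * (ages - 65)
     else config$age_band_log_hr[as.character(band)]) +
    config$cci_log_hr * cci +
    med_term + comed_term
  event_time <- with_seed(stream_seed(seed, 6L), rexp(n) / exp(loghaz))
  withdraw_time <- with_seed(stream_seed(seed, 7L), {
    if (config$censoring$annual_rate > 0)
      rexp(n) / config$censoring$annual_rate else rep(Inf, n)
  })

  admin_end <- as.Date(config$censoring$admin_end)
  event_date <- STUDY_START + round(event_time * 365.25)
  exit_date <- STUDY_START + round(withdraw_time * 365.25)
  exit_date[exit_date > admin_end] <- NA

  # -- cohort-entry plumbing ----------------------------------------------
  acc <- as.Date(config$accrual_window)
  # treatment initiation leaves room for the two monthly refills that the
  # entry criteria require within the accrual year
  misc <- with_seed(stream_seed(seed, 8L), {
    list(index = acc[1] + floor(runif(n) * as.numeric(acc[2] - 60 - acc[1] + 1)),
         compliant = rbinom(n, 1, config$claims_compliance) == 1,
         prior_cancer = rbinom(n, 1, config$prior_cancer_prob) == 1,
         com_day = floor(runif(n) * 365),   # day in 2003 for comorbidity dx
         u_extra = runif(n))
  })

  persons <- data.frame(person_id = seq_len(n), sex = "M",
                        birth_year = birth_year,
                        exit_date = exit_date,
                        stringsAsFactors = FALSE)
  covariates <- data.frame(person_id = seq_len(n),
                           age_years = as.integer(ages),
                           age_band = band,
                           copd = copd,
                           cci_score = cci,
                           flags,
                           inhaled_class = inhaled_class,
                           rescue_use = med_state$rescue,
                           statin = med_state$statin,
                           aspirin = med_state$aspirin,
                           steroid_oral = med_state$steroid_oral,
                           nsaid = med_state$nsaid,
                           compliant = misc$compliant,
                           prior_cancer = misc$prior_cancer,
                           index_date = as.Date(ifelse(copd == 1, misc$index,
                                                       NA), origin = "1970-01-01"),
                           stringsAsFactors = FALSE)
  hidden_truth <- data.frame(person_id = seq_len(n),
                             copd = copd,
                             smoking = M$smoking,
                             alcohol = M$alcohol,
                             bmi = M$bmi,
                             event_time_years = event_time,
                             withdraw_time_years = withdraw_time,
                             event_date = event_date,
                             stringsAsFactors = FALSE)

  bundle <- structure(list(persons = persons,
                           diagnosis_claims = NULL,
                           prescription_claims = NULL,
                           covariates = covariates,
                           hidden_truth = hidden_truth,
                           config = config),
                      class = "claims_bundle")
  if (config$claims)
    bundle <- add_claim_rows(bundle, med_state, misc)
  bundle
}

# Materialize diagnosis and prescription claim rows from the simulated
# person-level state.
add_claim_rows <- function(bundle, med_state, misc) {
  cov <- bundle$covariates
  truth <- bundle$hidden_truth
  config <- bundle$config
  com <- config$comorbidity_prevalences
  admin_end <- as.Date(config$censoring$admin_end)
  n <- nrow(cov)

  dx <- list()
  rx <- list()

  # comorbidity diagnoses in the year before the accrual window
  for (i in seq_len(nrow(com))) {
    has <- which(cov[[com$condition[i]]] == 1)
    if (!length(has)) next
    dx[[length(dx) + 1L]] <- data.frame(
      person_id = has,
      date = as.Date("2003-01-01") + misc$com_day[has],
      icd9_code = com$icd9[i], stringsAsFactors = FALSE)
  }

  # pre-study outcome diagnoses (to be excluded by the cohort builder)
  pc <- which(misc$prior_cancer)
  if (length(pc))
    dx[[length(dx) + 1L]] <- data.frame(
      person_id = pc, date = as.Date("2003-06-15"),
      icd9_code = "185", stringsAsFactors = FALSE)

  # observed outcome diagnoses: event occurred before withdrawal and
  # administrative end
  obs <- which(truth$event_date <= admin_end &
                 (is.na(bundle$persons$exit_date) |
                    truth$event_date <= bundle$persons$exit_date))
  if (length(obs))
    dx[[length(dx) + 1L]] <- data.frame(
      person_id = obs, date = truth$event_date[obs],
      icd9_code = "185", stringsAsFactors = FALSE)

  copd_ids <- which(cov$copd == 1)
  compliant <- which(cov$copd == 1 & cov$compliant)
  noncompliant <- setdiff(copd_ids, compliant)
  index <- cov$index_date

  # COPD diagnoses: two distinct dates around treatment start for persons
  # meeting the entry criteria, a single record otherwise
  copd_code <- function(ids) c("491", "492", "496")[1 + (ids %% 3)]
  if (length(compliant))
    dx[[length(dx) + 1L]] <- data.frame(
      person_id = rep(compliant, 2L),
      date = c(index[compliant] - 21, index[compliant] - 7),
      icd9_code = rep(copd_code(compliant), 2L), stringsAsFactors = FALSE)
  if (length(noncompliant))
    dx[[length(dx) + 1L]] <- data.frame(
      person_id = noncompliant, date = index[noncompliant] - 14,
      icd9_code = copd_code(noncompliant), stringsAsFactors = FALSE)

  # prescriptions: three claims of the assigned class starting at index;
  # "none" users receive an oral xanthine bronchodilator so that they still
  # satisfy the three-pharmacotherapy-claims criterion
  rx_class <- function(cls) ifelse(cls %in% c("none", "combination"),
                                   "XANTHINE", cls)
  if (length(compliant)) {
    cls1 <- rx_class(med_state$class[compliant])
    combo <- med_state$class[compliant] == "combination"
    cls1[combo] <- med_state$combo2[compliant, 1][combo]
    rx[[length(rx) + 1L]] <- data.frame(
      person_id = rep(compliant, 3L),
      date = c(index[compliant], index[compliant] + 30,
               index[compliant] + 60),
      drug_class = rep(cls1, 3L),
      days_supplied = 30L, stringsAsFactors = FALSE)
    if (any(combo)) {
      cid <- compliant[combo]
      cls2 <- med_state$combo2[cid, 2]
      rx[[length(rx) + 1L]] <- data.frame(
        person_id = rep(cid, 3L),
        date = c(index[cid] + 10, index[cid] + 40, index[cid] + 70),
        drug_class = rep(cls2, 3L),
        days_supplied = 30L, stringsAsFactors = FALSE)
    }
    resc <- compliant[med_state$rescue[compliant]]
    if (length(resc))
      rx[[length(rx) + 1L]] <- data.frame(
        person_id = resc, date = index[resc] + 45,
        drug_class = "SABA", days_supplied = 7L, stringsAsFactors = FALSE)
  }
  if (length(noncompliant)) {
    # too few claims to qualify
    rx[[length(rx) + 1L]] <- data.frame(
      person_id = noncompliant, date = index[noncompliant],
      drug_class = rx_class(med_state$class[noncompliant]),
      days_supplied = 30L, stringsAsFactors = FALSE)
  }

  # co-medication claims for every flagged person, spread over follow-up
  for (m in COMED_CLASSES) {
    has <- which(med_state[[m]] == 1)
    if (!length(has)) next
    rx[[length(rx) + 1L]] <- data.frame(
      person_id = has,
      date = STUDY_START + floor(misc$u_extra[has] * 700),
      drug_class = m, days_supplied = 30L, stringsAsFactors = FALSE)
  }

  dx <- do.call(rbind, dx)
  rx <- do.call(rbind, rx)
  dx <- dx[order(dx$person_id, dx$date, dx$icd9_code), , drop = FALSE]
  rx <- rx[order(rx$person_id, rx$date, rx$drug_class), , drop = FALSE]
  rownames(dx) <- rownames(rx) <- NULL
  bundle$diagnosis_claims <- dx
  bundle$prescription_claims <- rx
  bundle
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("Synthetic claims bundle\n")
  cat(sprintf("  persons:             %d\n", nrow(x$persons)))
  cat(sprintf("  COPD (true):         %d\n", sum(x$covariates$copd)))
  if (!is.null(x$diagnosis_claims))
    cat(sprintf("  diagnosis claims:    %d\n", nrow(x$diagnosis_claims)))
  if (!is.null(x$prescription_claims))
    cat(sprintf("  prescription claims: %d\n", nrow(x$prescription_claims)))
  invisible(x)
}

#' Export the main-study tables (confounders hidden)
#'
#' Returns the persons, diagnosis and prescription tables exactly as a
#' claims database would release them: no smoking, alcohol or BMI columns
#' and no ground truth.
#'
#' @param bundle a `claims_bundle`.
#' @return list of data.frames `persons`, `diagnosis_claims`,
#'   `prescription_claims`.
#' @export
export_main_study <- function(bundle) {
  stopifnot(inherits(bundle, "claims_bundle"))
  list(persons = bundle$persons,
       diagnosis_claims = bundle$diagnosis_claims,
       prescription_claims = bundle$prescription_claims)
}

#' Export the validation survey sample
#'
#' Draws a seeded subsample of the simulated population in which the
#' lifestyle confounders are revealed, emulating an external
#' health-interview survey.  Either a simple random `fraction` or exact
#' per-group sizes `n_by_group = c(copd =, control =)` may be requested;
#' the default configuration uses the study's survey sizes (312 exposed,
#' 804 unexposed).
#'
#' @param bundle a `claims_bundle`.
#' @param fraction simple-random-sample fraction (overrides `n_by_group`).
#' @param n_by_group named vector `c(copd =, control =)` of exact group
#'   sizes.
#' @param seed integer seed for sample membership.
#' @return data.frame with columns `person_id`, `D`, `age_years`,
#'   `age_band`, `cci_score`, `smoking`, `alcohol`, `bmi` and attribute
#'   `disjoint = FALSE` (the sample is drawn from the same population as
#'   the main study).
#' @export
export_validation_sample <- function(bundle, fraction = NULL,
                                     n_by_group = NULL, seed = 1L) {
  stopifnot(inherits(bundle, "claims_bundle"))
  cov <- bundle$covariates
  truth <- bundle$hidden_truth
  if (is.null(fraction) && is.null(n_by_group)) {
    v <- bundle$config$validation
    fraction <- v$fraction
    n_by_group <- v$n_by_group
  }
  n <- nrow(cov)
  if (!is.null(fraction)) {
    assert_prob(fraction, "fraction")
    idx <- if (fraction >= 1) seq_len(n) else
      with_seed(seed, sort(sample.int(n, round(fraction * n))))
    if (length(unique(cov$copd[idx])) < 2L)
      stop("sampling error: validation fraction too small to contain ",
           "both exposure groups", call. = FALSE)
  } else {
    exposed <- which(cov$copd == 1)
    unexposed <- which(cov$copd == 0)
    if (length(exposed) < n_by_group[["copd"]] ||
        length(unexposed) < n_by_group[["control"]])
      stop("sampling error: population too small for requested validation ",
           "group sizes", call. = FALSE)
    idx <- with_seed(seed, sort(c(
      sample(exposed, n_by_group[["copd"]]),
      sample(unexposed, n_by_group[["control"]]))))
  }
  out <- data.frame(person_id = cov$person_id[idx],
                    D = cov$copd[idx],
                    age_years = cov$age_years[idx],
                    age_band = cov$age_band[idx],
                    cci_score = cov$cci_score[idx],
                    smoking = truth$smoking[idx],
                    alcohol = truth$alcohol[idx],
                    bmi = truth$bmi[idx],
                    stringsAsFactors = FALSE)
  attr(out, "disjoint") <- FALSE
  out
}

#' Build an analysis cohort directly from simulation ground truth
#'
#' Fast path for estimator experiments: bypasses claim-level cohort
#' construction and derives the per-subject analysis table (exposure,
#' age, CCI, follow-up, event flag) straight from the generator's hidden
#' state, with every subject followed from the study start.  The lifestyle
#' confounders are deliberately omitted, mirroring the main database.
#'
#' @param bundle a `claims_bundle`.
#' @return data.frame with columns `person_id`, `D`, `age_years`,
#'   `age_band`, `cci_score`, `followup_years`, `event`.
#' @export
cohort_from_truth <- function(bundle) {
  stopifnot(inherits(bundle, "claims_bundle"))
  cov <- bundle$covariates
  truth <- bundle$hidden_truth
  admin_years <- as.numeric(as.Date(bundle$config$censoring$admin_end) -
                              STUDY_START) / 365.25
  censor <- pmin(truth$withdraw_time_years, admin_years)
  fu <- pmin(truth$event_time_years, censor)
  data.frame(person_id = cov$person_id,
             D = cov$copd,
             age_years = cov$age_years,
             age_band = cov$age_band,
             cci_score = cov$cci_score,
             followup_years = fu,
             event = as.integer(truth$event_time_years <= censor),
             stringsAsFactors = FALSE)
}
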