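# Cohort construction from claims tables: inclusion/exclusion criteria,
# Charlson comorbidity index, ratio age-sex matching, follow-up derivation.

#' Cohort entry criteria
#'
#' Defaults encode the study design: male, older than 50 years at the
#' index date, at least two COPD diagnosis claims on distinct dates
#' (ICD-9-CM 491/492/496), at least three COPD pharmacotherapy claims
#' during the 2004 accrual window, no COPD medication in the 365 days
#' before the index date (washout), and no outcome diagnosis (ICD-9-CM
#' 185) before the index date.
#'
#' Date conventions are half-open: a claim dated on the index date counts
#' as pre-index for comorbidity assessment and as post-index for
#' outcomes.  Ages are derived from birth year under the mid-year
#' (July 1) convention; the matching band uses the accrual-year age.
#'
#' @param min_age minimum age in years at index (51 = "older than 50").
#' @param sex required sex code.
#' @param min_dx_dates minimum number of distinct COPD diagnosis dates.
#' @param dx_code_prefixes ICD-9-CM prefixes identifying COPD.
#' @param min_rx_claims minimum COPD pharmacotherapy claims in the window.
#' @param copd_med_classes drug classes counting as COPD pharmacotherapy.
#' @param washout_days clean period before index with no COPD medication.
#' @param exclusion_dx_prefix outcome code prefix; any claim strictly
#'   before index excludes the person.
#' @param accrual_window Date vector of length 2.
#' @param admin_end administrative end of follow-up.
#' @return object of class `cohort_criteria`.
#' @export
cohort_criteria <- function(min_age = 51,
                            sex = "M",
                            min_dx_dates = 2L,
                            dx_code_prefixes = c("491", "492", "496"),
                            min_rx_claims = 3L,
                            copd_med_classes = c(INHALED_CLASSES, "XANTHINE"),
                            washout_days = 365L,
                            exclusion_dx_prefix = "185",
                            accrual_window = as.Date(c("2004-01-01",
                                                       "2004-12-31")),
                            admin_end = as.Date("2008-12-31")) {
  stopifnot(min_dx_dates >= 1, min_rx_claims >= 1,
            accrual_window[1] < accrual_window[2])
  structure(list(min_age = min_age, sex = sex,
                 min_dx_dates = as.integer(min_dx_dates),
                 dx_code_prefixes = dx_code_prefixes,
                 min_rx_claims = as.integer(min_rx_claims),
                 copd_med_classes = copd_med_classes,
                 washout_days = as.integer(washout_days),
                 exclusion_dx_prefix = exclusion_dx_prefix,
                 accrual_window = as.Date(accrual_window),
                 admin_end = as.Date(admin_end)),
            class = "cohort_criteria")
}

# Coerce a claims column to Date, reporting offending row numbers.
parse_dates <- function(x, table) {
  d <- tryCatch(as.Date(x), error = function(e) rep(as.Date(NA), length(x)))
  if (anyNA(d)) {
    bad <- which(is.na(d))
    stop("parse error: unparseable date in `", table, "` at row(s) ",
         paste(head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  }
  d
}

claims_tables <- function(claims) {
  if (inherits(claims, "claims_bundle"))
    claims <- export_main_study(claims)
  stopifnot(is.list(claims),
            all(c("persons", "diagnosis_claims") %in% names(claims)))
  claims$diagnosis_claims$date <-
    parse_dates(claims$diagnosis_claims$date, "diagnosis_claims")
  if (!is.null(claims$prescription_claims))
    claims$prescription_claims$date <-
      parse_dates(claims$prescription_claims$date, "prescription_claims")
  claims
}

# TRUE for codes matching any prefix.
code_matches <- function(code, prefixes) {
  out <- rep(FALSE, length(code))
  for (p in prefixes) out <- out | startsWith(code, p)
  out
}

#' Identify the exposed (COPD) cohort from claims
#'
#' Applies all entry criteria and returns one row per qualifying person.
#' The index date is the first qualifying COPD-pharmacotherapy claim in
#' the accrual window.
#'
#' @param claims a `claims_bundle` or list with `persons`,
#'   `diagnosis_claims`, `prescription_claims`.
#' @param criteria a [cohort_criteria()].
#' @return data.frame with columns `person_id`, `D` (all 1), `index_date`,
#'   `age_years` (at index), `age_band` (accrual-year age band).
#' @export
identify_copd_cohort <- function(claims, criteria = cohort_criteria()) {
  stopifnot(inherits(criteria, "cohort_criteria"))
  claims <- claims_tables(claims)
  persons <- claims$persons
  dx <- claims$diagnosis_claims
  rx <- claims$prescription_claims
  empty <- data.frame(person_id = integer(), D = integer(),
                      index_date = as.Date(character()),
                      age_years = integer(),
                      age_band = factor(character(), levels = AGE_BANDS))
  if (is.null(rx) || nrow(rx) == 0L) return(empty)

  acc <- criteria$accrual_window
  med <- rx[rx$drug_class %in% criteria$copd_med_classes, , drop = FALSE]

  # >= min_rx_claims pharmacotherapy claims inside the accrual window;
  # index = first such claim
  in_win <- med[med$date >= acc[1] & med$date <= acc[2], , drop = FALSE]
  n_rx <- table(in_win$person_id)
  cand <- as.integer(names(n_rx)[n_rx >= criteria$min_rx_claims])
  cand <- cand[cand %in% persons$person_id]   # ignore orphan claims
  if (!length(cand)) return(empty)
  first_rx <- tapply(in_win$date, in_win$person_id, min)
  index <- as.Date(c(unname(first_rx[as.character(cand)])), origin = "1970-01-01")

  # washout: no COPD medication in the washout window before index
  wash_start <- index - criteria$washout_days
  pre <- med[med$person_id %in% cand, , drop = FALSE]
  pre_idx <- index[match(pre$person_id, cand)]
  pre_start <- wash_start[match(pre$person_id, cand)]
  viol <- unique(pre$person_id[pre$date >= pre_start & pre$date < pre_idx])
  keep <- !(cand %in% viol)
  cand <- cand[keep]; index <- index[keep]
  if (!length(cand)) return(empty)

  # >= min_dx_dates distinct COPD diagnosis dates
  cdx <- dx[code_matches(dx$icd9_code, criteria$dx_code_prefixes) &
              dx$person_id %in% cand, , drop = FALSE]
  n_dates <- tapply(cdx$date, cdx$person_id,
                    function(d) length(unique(d)))
  ok_dx <- as.integer(names(n_dates)[n_dates >= criteria$min_dx_dates])
  keep <- cand %in% ok_dx
  cand <- cand[keep]; index <- index[keep]
  if (!length(cand)) return(empty)

  # demographic criteria
  p <- persons[match(cand, persons$person_id), , drop = FALSE]
  age <- age_at(p$birth_year, index)
  keep <- p$sex == criteria$sex & age >= criteria$min_age
  cand <- cand[keep]; index <- index[keep]
  age <- age[keep]; p <- p[keep, , drop = FALSE]
  if (!length(cand)) return(empty)

  # exclusion: outcome diagnosis strictly before index
  ex <- dx[code_matches(dx$icd9_code, criteria$exclusion_dx_prefix) &
             dx$person_id %in% cand, , drop = FALSE]
  if (nrow(ex)) {
    first_ex <- tapply(ex$date, ex$person_id, min)
    ex_date <- as.Date(c(unname(first_ex[as.character(cand)])), origin = "1970-01-01")
    keep <- is.na(ex_date) | ex_date >= index
    cand <- cand[keep]; index <- index[keep]
    age <- age[keep]; p <- p[keep, , drop = FALSE]
    if (!length(cand)) return(empty)
  }

  year0 <- as.integer(format(criteria$accrual_window[1], "%Y"))
  out <- data.frame(person_id = cand, D = 1L, index_date = index,
                    age_years = age,
                    age_band = age_band(year0 - p$birth_year))
  out <- out[order(out$person_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default comorbidity-to-ICD-9 code map for the Charlson index
#'
#' @param scheme weight scheme passed to [cci_weights()].
#' @return data.frame with columns `condition`, `prefixes`
#'   (comma-separated ICD-9-CM prefixes), `weight`.
#' @export
default_cci_map <- function(scheme = "unit") {
  prefixes <- list(
    mi = c("410", "412"), chf = "428", pvd = c("440", "441", "443"),
    cvd = as.character(430:438), dementia = "290",
    rheumatic = c("714.0", "710.0"),
    peptic_ulcer = c("531", "532", "533", "534"), mild_liver = "571",
    diabetes = c("250.0", "250.1", "250.2", "250.3"),
    diabetes_complicated = paste0("250.", 4:9),
    paraplegia = c("342", "344"), renal = c("585", "586"),
    severe_liver = "572",
    metastatic_cancer = as.character(196:199), aids = "042")
  w <- cci_weights(scheme)
  data.frame(condition = names(prefixes),
             prefixes = vapply(prefixes, paste, "", collapse = ","),
             weight = as.numeric(w[names(prefixes)]),
             stringsAsFactors = FALSE)
}

#' Charlson comorbidity index from pre-index diagnosis claims
#'
#' A condition flag is set when at least one diagnosis claim matching its
#' code set is dated on or before the person's index date; the score is
#' the weighted sum of flags.
#'
#' @param claims a `claims_bundle` or claims list.
#' @param cohort data.frame with `person_id` and `index_date`.
#' @param code_map data.frame as [default_cci_map()].
#' @return `cohort` with appended logical flag columns (one per
#'   condition) and numeric `cci_score`.
#' @export
compute_cci <- function(claims, cohort, code_map = default_cci_map()) {
  stopifnot(all(c("condition", "prefixes", "weight") %in% names(code_map)))
  if (anyNA(code_map$weight) || any(!nzchar(code_map$condition)))
    stop("configuration error: malformed comorbidity code map",
         call. = FALSE)
  claims <- claims_tables(claims)
  dx <- claims$diagnosis_claims
  dx <- dx[dx$person_id %in% cohort$person_id, , drop = FALSE]
  idx <- cohort$index_date[match(dx$person_id, cohort$person_id)]
  dx <- dx[dx$date <= idx, , drop = FALSE]   # on-index counts as pre-index

  score <- numeric(nrow(cohort))
  for (i in seq_len(nrow(code_map))) {
    pref <- strsplit(code_map$prefixes[i], ",", fixed = TRUE)[[1]]
    has <- unique(dx$person_id[code_matches(dx$icd9_code, pref)])
    flag <- cohort$person_id %in% has
    cohort[[code_map$condition[i]]] <- flag
    score <- score + code_map$weight[i] * flag
  }
  cohort$cci_score <- score
  cohort
}

#' Match unexposed controls to the exposed cohort
#'
#' Draws `ratio` controls per case with the same sex and age band,
#' without replacement, using a seeded shuffle per stratum; within a
#' stratum cases are processed in index-date order and candidates with an
#' outcome diagnosis before the case's index date are discarded.
#' Controls inherit the matched case's index date.
#'
#' @param cases output of [identify_copd_cohort()].
#' @param claims a `claims_bundle` or claims list supplying the control
#'   pool (persons with no COPD diagnosis claim and not among the cases).
#' @param ratio controls per case.
#' @param seed integer seed.
#' @param criteria a [cohort_criteria()] (for sex/age rules and codes).
#' @return data.frame of control rows: `person_id`, `D` (all 0),
#'   `index_date`, `age_years`, `age_band`, `matched_case`.
#' @export
match_controls <- function(cases, claims, ratio = 3L, seed = 1L,
                           criteria = cohort_criteria()) {
  stopifnot(ratio >= 1)
  empty <- data.frame(person_id = integer(), D = integer(),
                      index_date = as.Date(character()),
                      age_years = integer(),
                      age_band = factor(character(), levels = AGE_BANDS),
                      matched_case = integer())
  if (nrow(cases) == 0L) return(empty)
  claims <- claims_tables(claims)
  persons <- claims$persons
  dx <- claims$diagnosis_claims

  copd_ever <- unique(dx$person_id[code_matches(dx$icd9_code,
                                                criteria$dx_code_prefixes)])
  year0 <- as.integer(format(criteria$accrual_window[1], "%Y"))
  pool <- persons[!(persons$person_id %in% cases$person_id) &
                    !(persons$person_id %in% copd_ever) &
                    persons$sex == criteria$sex, , drop = FALSE]
  pool$age_band <- age_band(year0 - pool$birth_year)
  pool <- pool[!is.na(pool$age_band), , drop = FALSE]

  ex <- dx[code_matches(dx$icd9_code, criteria$exclusion_dx_prefix) &
             dx$person_id %in% pool$person_id, , drop = FALSE]
  first_ex <- if (nrow(ex)) tapply(ex$date, ex$person_id, min) else NULL
  pool$first_cancer <- if (is.null(first_ex)) as.Date(NA) else
    as.Date(c(unname(first_ex[as.character(pool$person_id)])), origin = "1970-01-01")

  out <- vector("list", length(AGE_BANDS))
  for (b in AGE_BANDS) {
    cs <- cases[cases$age_band == b, , drop = FALSE]
    if (nrow(cs) == 0L) next
    cs <- cs[order(cs$index_date, cs$person_id), , drop = FALSE]
    cand <- pool[pool$age_band == b, , drop = FALSE]
    cand <- cand[order(cand$person_id), , drop = FALSE]
    perm <- with_seed(stream_seed(seed, match(b, AGE_BANDS)),
                      sample.int(nrow(cand)))
    cand <- cand[perm, , drop = FALSE]
    ptr <- 1L
    picked_id <- integer(nrow(cs) * ratio)
    picked_case <- integer(nrow(cs) * ratio)
    picked_idx <- rep(as.Date(NA), nrow(cs) * ratio)
    k <- 0L
    for (i in seq_len(nrow(cs))) {
      need <- ratio
      while (need > 0L) {
        if (ptr > nrow(cand))
          stop("matching error: control pool exhausted in stratum sex=",
               criteria$sex, ", age band ", b, " (shortfall ",
               (nrow(cs) - i) * ratio + need, " controls)", call. = FALSE)
        ok <- is.na(cand$first_cancer[ptr]) ||
          cand$first_cancer[ptr] >= cs$index_date[i]
        if (ok) {
          k <- k + 1L
          picked_id[k] <- cand$person_id[ptr]
          picked_case[k] <- cs$person_id[i]
          picked_idx[k] <- cs$index_date[i]
          need <- need - 1L
        }
        ptr <- ptr + 1L
      }
    }
    sel <- persons[match(picked_id[seq_len(k)], persons$person_id), ,
                   drop = FALSE]
    out[[match(b, AGE_BANDS)]] <- data.frame(
      person_id = picked_id[seq_len(k)], D = 0L,
      index_date = picked_idx[seq_len(k)],
      age_years = age_at(sel$birth_year, picked_idx[seq_len(k)]),
      age_band = factor(b, levels = AGE_BANDS),
      matched_case = picked_case[seq_len(k)])
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Derive follow-up time and event status
#'
#' Follow-up runs from the index date to the earliest of the first
#' outcome diagnosis (ICD-9-CM 185, dated on or after index), the
#' person's exit (death/withdrawal) date, and the administrative end of
#' the study; the event flag is set only when the outcome date attains
#' the minimum.
#'
#' @param cohort data.frame with `person_id`, `index_date`.
#' @param claims a `claims_bundle` or claims list.
#' @param admin_end administrative censoring date.
#' @param outcome_prefix ICD-9-CM prefix of the outcome diagnosis.
#' @return `cohort` with appended `followup_years`, `event`,
#'   `censor_reason` (`"event"`, `"death_or_withdrawal"`, `"admin_end"`).
#' @export
compute_followup <- function(cohort, claims,
                             admin_end = as.Date("2008-12-31"),
                             outcome_prefix = "185") {
  claims <- claims_tables(claims)
  dx <- claims$diagnosis_claims
  persons <- claims$persons
  if (any(cohort$index_date > admin_end))
    stop("data-consistency error: index date after administrative end",
         call. = FALSE)

  oc <- dx[code_matches(dx$icd9_code, outcome_prefix) &
             dx$person_id %in% cohort$person_id, , drop = FALSE]
  if (nrow(oc)) {
    first_all <- tapply(as.numeric(oc$date), oc$person_id, min)
    pid <- as.integer(names(first_all))
    idx0 <- as.numeric(cohort$index_date[match(pid, cohort$person_id)])
    bad <- pid[first_all < idx0]
    if (length(bad))
      stop("data-consistency error: outcome diagnosis precedes index for ",
           "person(s) ", paste(head(bad, 5L), collapse = ", "),
           " (should have been excluded upstream)", call. = FALSE)
  }
  first_ev <- if (nrow(oc)) tapply(oc$date, oc$person_id, min) else NULL
  ev_date <- if (is.null(first_ev)) rep(as.Date(NA), nrow(cohort)) else
    as.Date(c(unname(first_ev[as.character(cohort$person_id)])), origin = "1970-01-01")

  exit <- persons$exit_date[match(cohort$person_id, persons$person_id)]
  if (is.null(exit)) exit <- rep(as.Date(NA), nrow(cohort))
  exit_n <- as.numeric(exit); exit_n[is.na(exit_n)] <- Inf
  ev_n <- as.numeric(ev_date); ev_n[is.na(ev_n)] <- Inf
  censor_n <- pmin(exit_n, as.numeric(admin_end))
  end_n <- pmin(ev_n, censor_n)
  event <- as.integer(ev_n <= censor_n)
  fu <- (end_n - as.numeric(cohort$index_date)) / 365.25
  fu[fu <= 0] <- 0.5 / 365.25    # same-day event: half a day of exposure
  cohort$followup_years <- fu
  cohort$event <- event
  cohort$censor_reason <- ifelse(event == 1, "event",
                                 ifelse(end_n == exit_n,
                                        "death_or_withdrawal", "admin_end"))
  cohort
}

#' Build the full matched analysis cohort from claims
#'
#' Orchestrates [identify_copd_cohort()], [match_controls()],
#' [compute_cci()] and [compute_followup()].
#'
#' @inheritParams match_controls
#' @param code_map comorbidity map for [compute_cci()].
#' @return data.frame with one row per subject (cases then controls).
#' @export
build_cohort <- function(claims, criteria = cohort_criteria(), ratio = 3L,
                         seed = 1L, code_map = default_cci_map()) {
  cases <- identify_copd_cohort(claims, criteria)
  controls <- match_controls(cases, claims, ratio = ratio, seed = seed,
                             criteria = criteria)
  controls$matched_case <- NULL
  cohort <- rbind(cases, controls)
  cohort <- compute_cci(claims, cohort, code_map)
  cohort <- compute_followup(cohort, claims, admin_end = criteria$admin_end,
                             outcome_prefix = criteria$exclusion_dx_prefix)
  rownames(cohort) <- NULL
  cohort
}
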