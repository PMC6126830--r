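# Fixture builders shared across test files.  All data is constructed in
# code; person 1 is the canonical qualifying COPD case (male, born 1932,
# two diagnosis dates, three pharmacotherapy claims from 2004-02-01).

fixture_persons <- function(ids, birth_year = 1932, sex = "M",
                            exit_date = as.Date(NA)) {
  k <- length(ids)
  data.frame(person_id = ids, sex = rep_len(sex, k),
             birth_year = rep_len(birth_year, k),
             exit_date = rep_len(exit_date, k), stringsAsFactors = FALSE)
}

dx_rows <- function(id, dates, code) {
  k <- max(length(id), length(dates))
  data.frame(person_id = rep_len(id, k), date = rep_len(as.Date(dates), k),
             icd9_code = rep_len(code, k), stringsAsFactors = FALSE)
}

rx_rows <- function(id, dates, drug_class = "SAMA", days = 30L) {
  k <- max(length(id), length(dates))
  data.frame(person_id = rep_len(id, k), date = rep_len(as.Date(dates), k),
             drug_class = rep_len(drug_class, k),
             days_supplied = rep_len(days, k), stringsAsFactors = FALSE)
}

# A minimal claims list around the canonical case plus optional extras.
fixture_claims <- function(persons, dx, rx) {
  list(persons = persons, diagnosis_claims = dx, prescription_claims = rx)
}

qualifying_case_claims <- function() {
  fixture_claims(
    fixture_persons(1L),
    dx_rows(1L, c("2004-02-01", "2004-03-01"), "491"),
    rx_rows(1L, c("2004-02-01", "2004-03-01", "2004-04-01")))
}

# Two-group exponential survival data with censoring at a fixed time;
# closed-form rate-ratio oracle available as log((d1/PY1)/(d0/PY0)).
exp_two_group <- function(n_per_group, rate0, rate1, cens_time = 5,
                          seed = 1) {
  set.seed(seed)
  t0 <- rexp(n_per_group, rate0)
  t1 <- rexp(n_per_group, rate1)
  data.frame(
    D = rep(c(0L, 1L), each = n_per_group),
    followup_years = pmin(c(t0, t1), cens_time),
    event = as.integer(c(t0, t1) <= cens_time))
}
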