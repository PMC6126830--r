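# Descriptive statistics and table/figure-data assembly.

#' Pearson chi-square test on a contingency table
#'
#' Classical Pearson statistic without continuity correction,
#' `df = (r - 1)(k - 1)`, upper-tail p-value.
#'
#' @param table matrix (or coercible) of non-negative counts, at least
#'   2 x 2.
#' @return list with `statistic`, `df`, `p`.
#' @export
pearson_chi_square <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m)))
    stop("domain error: counts must be non-negative integers",
         call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("domain error: zero row or column margin", call. = FALSE)
  ht <- stats::chisq.test(m, correct = FALSE)
  if (any(ht$expected <= 0))
    stop("domain error: non-positive expected count", call. = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

fmt_hr <- function(hr, lo, hi)
  sprintf("%.2f (%.2f-%.2f)", round(hr, 2), round(lo, 2), round(hi, 2))

#' Assemble the crude/adjusted/calibrated hazard-ratio table
#'
#' Builds the summary table of the matched-cohort analysis: events over
#' totals, incidence per 100,000 person-years, the crude and
#' propensity-adjusted hazard ratios, and the two-stage calibrated
#' hazard ratio, by exposure group.  Hazard ratios are formatted to two
#' decimals and incidences to integers; full precision is preserved in
#' the `values` attribute.
#'
#' @param cohort analysis cohort with `D`, `followup_years`, `event`.
#' @param crude,adjusted `hazard_fit` objects.
#' @param calibrated a `calibration_result`.
#' @return data.frame with rows `Yes/Total`,
#'   `Incidence (100,000 person-years)`, `Crude HR`, `Adjusted HR`,
#'   `Two-stage method adjusted HR` and columns `row`, `unexposed`,
#'   `exposed`.
#' @export
build_table2 <- function(cohort, crude, adjusted, calibrated) {
  for (nm in c("crude", "adjusted", "calibrated")) {
    obj <- switch(nm, crude = crude, adjusted = adjusted,
                  calibrated = calibrated)
    if (is.null(obj))
      stop("missing input for row `", nm, "`", call. = FALSE)
  }
  stopifnot(inherits(crude, "hazard_fit"),
            inherits(adjusted, "hazard_fit"),
            inherits(calibrated, "calibration_result"))
  by_d <- split(cohort, cohort$D)
  ev <- vapply(by_d, function(g) sum(g$event), 0)
  tot <- vapply(by_d, nrow, 0L)
  py <- vapply(by_d, function(g) sum(g$followup_years), 0)
  inc <- incidence_rate(ev, py)
  cal_ci <- if (!is.null(calibrated$ci)) exp(calibrated$ci) else
    c(NA_real_, NA_real_)
  tab <- data.frame(
    row = c("Yes/Total", "Incidence (100,000 person-years)", "Crude HR",
            "Adjusted HR", "Two-stage method adjusted HR"),
    unexposed = c(sprintf("%d/%d", as.integer(ev[["0"]]), tot[["0"]]),
                  sprintf("%.0f", inc[["0"]]), "1.00", "1.00", "1.00"),
    exposed = c(sprintf("%d/%d", as.integer(ev[["1"]]), tot[["1"]]),
                sprintf("%.0f", inc[["1"]]),
                fmt_hr(crude$hr, crude$ci[1], crude$ci[2]),
                fmt_hr(adjusted$hr, adjusted$ci[1], adjusted$ci[2]),
                if (all(is.finite(cal_ci)))
                  fmt_hr(calibrated$hr_star, cal_ci[1], cal_ci[2])
                else sprintf("%.2f", round(calibrated$hr_star, 2))),
    stringsAsFactors = FALSE)
  attr(tab, "values") <- list(events = ev, totals = tot, person_years = py,
                              incidence = inc, crude_hr = crude$hr,
                              adjusted_hr = adjusted$hr,
                              calibrated_hr = calibrated$hr_star)
  tab
}

#' Cumulative-hazard curve data by group
#'
#' Nelson-Aalen cumulative hazard per exposure group, exported as plain
#' data (plotting is left to the user).
#'
#' @param cohort analysis cohort with `followup_years`, `event`.
#' @param group name of the grouping column.
#' @return data.frame with columns `group`, `time`, `cumhaz`,
#'   non-decreasing in time within group.
#' @export
hazard_curves <- function(cohort, group = "D") {
  if (!group %in% names(cohort))
    stop("unknown group column `", group, "`", call. = FALSE)
  sf <- survfit(as.formula(paste("Surv(followup_years, event) ~", group)),
                data = cohort, ctype = 1)
  strata <- if (is.null(sf$strata)) {
    rep(unique(cohort[[group]])[1], length(sf$time))
  } else {
    rep(sub(paste0("^", group, "="), "", names(sf$strata)), sf$strata)
  }
  data.frame(group = strata, time = sf$time, cumhaz = sf$cumhaz,
             stringsAsFactors = FALSE)
}
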