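# Incidence, propensity-score and Cox proportional-hazards estimation.

#' Incidence rate per person-time
#'
#' @param events number of outcome events.
#' @param person_years total person-time at risk (> 0).
#' @param scale person-time units of the reported rate (default 100,000
#'   person-years).
#' @return events / person_years * scale.
#' @export
incidence_rate <- function(events, person_years, scale = 1e5) {
  if (!is.numeric(person_years) || any(person_years <= 0))
    stop("domain error: `person_years` must be > 0", call. = FALSE)
  if (any(events < 0)) stop("domain error: `events` must be >= 0",
                            call. = FALSE)
  events / person_years * scale
}

#' Fit a propensity-score model
#'
#' Maximum-likelihood logistic regression of the exposure indicator on
#' covariates.  With only the shared covariates E the fitted score is the
#' error-prone score PS_c; adding the confounders M observed in the
#' validation sample gives the gold-standard score PS_m.
#'
#' @param data data.frame containing the exposure column and covariates.
#' @param covariates character vector of covariate column names; empty
#'   for an intercept-only model.
#' @param exposure name of the 0/1 exposure column.
#' @param variant `"error_prone"` or `"gold_standard"` tag.
#' @return object of class `propensity_model`: list with `coefficients`,
#'   `scores` (in (0,1), one per row of `data`), `covariates`, `variant`,
#'   `fit` (the underlying `glm`).
#' @export
fit_propensity <- function(data, covariates, exposure = "D",
                           variant = c("error_prone", "gold_standard")) {
  variant <- match.arg(variant)
  if (!exposure %in% names(data))
    stop("missing exposure column `", exposure, "`", call. = FALSE)
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(unique(data[[exposure]])) < 2L)
    stop("need both exposure groups to fit a propensity model",
         call. = FALSE)
  for (v in covariates)
    if (anyNA(data[[v]]))
      stop("missing values in covariate `", v, "`", call. = FALSE)
  rhs <- if (length(covariates))
    paste(covariates, collapse = " + ") else "1"
  fml <- as.formula(paste(exposure, "~", rhs))
  fit <- glm(fml, data = data, family = binomial())
  scores <- as.numeric(fitted(fit))
  if (!fit$converged || any(scores <= 1e-12) || any(scores >= 1 - 1e-12))
    stop("propensity model did not converge cleanly (possible perfect ",
         "separation); consider penalized estimation or coarser covariates",
         call. = FALSE)
  structure(list(coefficients = coef(fit), scores = scores,
                 covariates = covariates, variant = variant, fit = fit),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("Propensity model (%s), %d subjects\n", x$variant,
              length(x$scores)))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood estimation via [survival::coxph()].  The crude
#' model uses the exposure indicator alone; the propensity-adjusted model
#' is `~ D + PS` with the score entered as a continuous covariate, the
#' form required by the two-stage calibration algebra
#' `H(t | D, PS) = H0(t) exp(beta * D + beta_c * PS)`.
#'
#' @param cohort data.frame with `followup_years`, `event`, the exposure
#'   column and any adjustment columns.
#' @param terms character vector of right-hand-side terms (first should
#'   be the exposure indicator).
#' @param ties tie-handling method (default Efron).
#' @param strata optional column name for a stratified baseline hazard
#'   (e.g. propensity-score quintiles).
#' @return object of class `hazard_fit`: coefficients, standard errors,
#'   `hr` = exp(coef of the first term) with Wald 95\% CI, `n`, `events`,
#'   `ties`, and the underlying `coxph` fit.
#' @export
fit_cox <- function(cohort, terms = "D", ties = c("efron", "breslow"),
                    strata = NULL) {
  ties <- match.arg(ties)
  stopifnot(all(c("followup_years", "event") %in% names(cohort)))
  if (any(cohort$followup_years <= 0))
    stop("domain error: non-positive follow-up time", call. = FALSE)
  if (sum(cohort$event) == 0L)
    stop("zero events: hazard model is not estimable", call. = FALSE)
  rhs <- paste(terms, collapse = " + ")
  if (!is.null(strata))
    rhs <- paste0(rhs, " + strata(", strata, ")")
  fml <- as.formula(paste("Surv(followup_years, event) ~", rhs))
  fit <- coxph(fml, data = cohort, ties = ties,
               control = survival::coxph.control(eps = 1e-10,
                                                 iter.max = 50))
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  ci <- cbind(exp(beta - 1.96 * se), exp(beta + 1.96 * se))
  structure(list(coefficients = beta, se = unname(se),
                 hr = unname(exp(beta[1])),
                 ci = c(ci[1, 1], ci[1, 2]),
                 hr_table = data.frame(term = names(beta),
                                       hr = exp(beta),
                                       ci_low = ci[, 1], ci_high = ci[, 2],
                                       p = 2 * stats::pnorm(-abs(beta / se)),
                                       row.names = NULL),
                 n = fit$n, events = fit$nevent, ties = ties, fit = fit),
            class = "hazard_fit")
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): n = %d, events = %d\n", x$ties, x$n,
              x$events))
  cat(sprintf("  %s HR = %.3f (95%% CI %.3f-%.3f)\n",
              names(x$coefficients)[1], x$hr, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Crude and propensity-adjusted hazard ratios for a matched cohort
#'
#' Convenience wrapper fitting the error-prone propensity score on the
#' shared covariates (age band + CCI by default, the study's adjustment
#' set) and the crude and PS-adjusted Cox models.
#'
#' @param cohort analysis cohort with `D`, `followup_years`, `event` and
#'   the covariate columns.
#' @param ps_covariates covariates of the propensity model.
#' @param ties passed to [fit_cox()].
#' @return list with `ps` (propensity_model), `crude` and `adjusted`
#'   (hazard_fit objects), and the cohort with a `PS` column appended.
#' @export
fit_cohort_models <- function(cohort,
                              ps_covariates = c("age_band", "cci_score"),
                              ties = "efron") {
  ps <- fit_propensity(cohort, ps_covariates, variant = "error_prone")
  cohort$PS <- ps$scores
  list(ps = ps,
       crude = fit_cox(cohort, "D", ties = ties),
       adjusted = fit_cox(cohort, c("D", "PS"), ties = ties),
       cohort = cohort)
}
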