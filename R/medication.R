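# Medication-exposure classification and the multivariable Cox model for
# the exposed cohort.

#' Default drug-code to medication-class map
#'
#' Maps prescription `drug_class` codes to the analysis categories:
#' the five inhaled classes, other COPD pharmacotherapy (oral xanthines,
#' category `"copd_other"`), and the co-medications (statin, aspirin,
#' oral steroid, NSAID).  In real claims data the keys would be ATC
#' codes (e.g. statins C10AA01-C10AA05); the synthetic generator emits
#' the class labels directly.
#'
#' @return data.frame with columns `code`, `category`.
#' @export
default_class_map <- function() {
  data.frame(
    code = c(INHALED_CLASSES, "XANTHINE",
             "statin", paste0("C10AA0", 1:5),
             "aspirin", "steroid_oral", "nsaid"),
    category = c(INHALED_CLASSES, "copd_other",
                 rep("statin", 6), "aspirin", "steroid_oral", "nsaid"),
    stringsAsFactors = FALSE)
}

#' Classify medication exposure of the exposed cohort
#'
#' Applies the study's exposure rules to prescription claims:
#' * an inhaled claim qualifies only if its own days supplied exceed
#'   `min_days` (default 14, strictly);
#' * a person's inhaled class is their unique qualifying class;
#' * users of a long-acting class (LAMA, LABA, LABA+ICS) may additionally
#'   hold short-acting (SABA/SAMA) claims of at most `min_days` each as
#'   on-demand rescue medication (`rescue_use` flag) without losing their
#'   class;
#' * two distinct qualifying classes outside that allowance mark the
#'   person `excluded_combination` (omitted from the medication model);
#' * the stationary-medication rule requires at least `min_claims`
#'   qualifying claims of the class within `window_days` of the first
#'   qualifying claim; persons failing it are classed `"none"`;
#' * co-medication flags (statin, aspirin, oral steroid, NSAID) require
#'   at least one claim, with no duration threshold, before the person's
#'   cutoff date (event or censoring) when `cutoff` is supplied.
#'
#' Unmapped drug codes raise a warning and are kept in an
#' `"unclassified"` bucket, never silently dropped.
#'
#' @param rx_claims data.frame with `person_id`, `date`, `drug_class`,
#'   `days_supplied`.
#' @param person_ids persons to classify (default: all in `rx_claims`).
#' @param class_map data.frame as [default_class_map()].
#' @param min_days per-claim days-supplied threshold (claim qualifies iff
#'   `days_supplied > min_days`).
#' @param min_claims stationary-medication claim count.
#' @param window_days stationary-medication window.
#' @param cutoff optional data.frame `person_id`, `cutoff_date`;
#'   co-medication claims after it are ignored.
#' @param accumulate if TRUE, the threshold applies to the person-level
#'   accumulated days per class rather than per claim (alternative
#'   reading of the duration rule).
#' @return data.frame (one row per person): `person_id`,
#'   `inhaled_class` (factor: SAMA, SABA, LAMA, LABA, LABA_ICS, none),
#'   `rescue_use`, `excluded_combination`, `unclassified`,
#'   `qualifying_claims`, and logical co-medication flags.
#' @export
classify_medication_exposure <- function(rx_claims,
                                         person_ids = NULL,
                                         class_map = default_class_map(),
                                         min_days = 14,
                                         min_claims = 3L,
                                         window_days = 365L,
                                         cutoff = NULL,
                                         accumulate = FALSE) {
  rx <- rx_claims
  rx$date <- parse_dates(rx$date, "rx_claims")
  if (is.null(person_ids)) person_ids <- sort(unique(rx$person_id))
  rx <- rx[rx$person_id %in% person_ids, , drop = FALSE]

  cat_of <- class_map$category[match(rx$drug_class, class_map$code)]
  unknown <- is.na(cat_of)
  if (any(unknown)) {
    warning("unmapped drug code(s): ",
            paste(unique(rx$drug_class[unknown]), collapse = ", "),
            "; kept as 'unclassified'", call. = FALSE)
    cat_of[unknown] <- "unclassified"
  }
  rx$category <- cat_of

  inh <- rx[rx$category %in% INHALED_CLASSES, , drop = FALSE]
  if (accumulate) {
    acc <- stats::aggregate(days_supplied ~ person_id + category, inh, sum)
    qual_ok <- acc[acc$days_supplied > min_days, c("person_id", "category")]
    inh$qual <- paste(inh$person_id, inh$category) %in%
      paste(qual_ok$person_id, qual_ok$category)
  } else {
    inh$qual <- inh$days_supplied > min_days
  }
  quals <- inh[inh$qual, , drop = FALSE]

  out <- data.frame(person_id = person_ids)
  out$inhaled_class <- "none"
  out$rescue_use <- FALSE
  out$excluded_combination <- FALSE
  out$unclassified <- out$person_id %in%
    rx$person_id[rx$category == "unclassified"]
  out$qualifying_claims <- 0L

  if (nrow(quals)) {
    split_q <- split(quals, quals$person_id)
    for (pid_chr in names(split_q)) {
      q <- split_q[[pid_chr]]
      i <- match(pid_chr, as.character(out$person_id))
      classes <- unique(q$category)
      if (length(classes) > 1L) {
        out$excluded_combination[i] <- TRUE
        next
      }
      # stationary-medication rule within the first treatment year
      first <- min(q$date)
      n_window <- sum(q$date <= first + window_days)
      out$qualifying_claims[i] <- n_window
      if (n_window >= min_claims) out$inhaled_class[i] <- classes
    }
  }

  # rescue allowance: long-acting users with sub-threshold short-acting
  # claims keep their class, flagged as rescue users
  sa <- inh[inh$category %in% c("SABA", "SAMA") & !inh$qual, , drop = FALSE]
  long_users <- out$person_id[out$inhaled_class %in% LONG_ACTING]
  out$rescue_use <- out$person_id %in% intersect(sa$person_id, long_users)

  # co-medication flags
  co <- rx[rx$category %in% COMED_CLASSES, , drop = FALSE]
  if (!is.null(cutoff)) {
    cut <- cutoff$cutoff_date[match(co$person_id, cutoff$person_id)]
    co <- co[!is.na(cut) & co$date <= cut, , drop = FALSE]
  }
  for (m in COMED_CLASSES)
    out[[m]] <- out$person_id %in% co$person_id[co$category == m]

  out$inhaled_class <- factor(out$inhaled_class,
                              levels = c("none", INHALED_CLASSES))
  out
}

#' Multivariable Cox model of medication effects in the exposed cohort
#'
#' Single Cox fit with simultaneous indicators for the five inhaled
#' classes (reference: no inhaled class), the four co-medications, the
#' CCI score and continuous age.  Persons flagged `excluded_combination`
#' are removed; indicator terms with no exposed subjects are dropped
#' with a warning.
#'
#' @param copd_cohort exposed-cohort rows with `person_id`,
#'   `followup_years`, `event`, `cci_score`, `age_years`.
#' @param profiles output of [classify_medication_exposure()].
#' @param ties Cox tie handling.
#' @return list: `fit` (a `hazard_fit`), `table` (one row per model
#'   term: `term`, `hr`, `ci_low`, `ci_high`, `p`), `n`, `events`,
#'   `n_excluded_combination`.
#' @export
fit_medication_cox <- function(copd_cohort, profiles, ties = "efron") {
  dat <- merge(copd_cohort, profiles, by = "person_id")
  n_excl <- sum(dat$excluded_combination)
  dat <- dat[!dat$excluded_combination, , drop = FALSE]

  for (cl in INHALED_CLASSES)
    dat[[cl]] <- as.integer(dat$inhaled_class == cl)
  for (m in COMED_CLASSES)
    dat[[m]] <- as.integer(dat[[m]])

  terms <- c(INHALED_CLASSES, COMED_CLASSES)
  keep <- vapply(terms, function(t) sum(dat[[t]]) > 0L, TRUE)
  if (any(!keep))
    warning("dropping term(s) with no exposed subjects: ",
            paste(terms[!keep], collapse = ", "), call. = FALSE)
  terms <- c(terms[keep], "cci_score", "age_years")

  fit <- fit_cox(dat, terms, ties = ties)
  tab <- fit$hr_table
  tab$term[tab$term == "LABA_ICS"] <- "LABA plus ICS"
  tab$term[tab$term == "steroid_oral"] <- "Steroid"
  tab$term[tab$term == "statin"] <- "Statin"
  tab$term[tab$term == "aspirin"] <- "Aspirin"
  tab$term[tab$term == "nsaid"] <- "NSAID"
  tab$term[tab$term == "cci_score"] <- "CCI score"
  tab$term[tab$term == "age_years"] <- "Age (continuous)"
  list(fit = fit, table = tab, n = fit$n, events = fit$events,
       n_excluded_combination = n_excl)
}
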