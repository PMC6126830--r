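# CSV/YAML interchange for the simulated tables and configuration.

#' Write a claims bundle to CSV files
#'
#' Emits `persons.csv`, `diagnoses.csv`, `prescriptions.csv` (the
#' main-study export, confounders hidden), `validation.csv` (the survey
#' sample) and `truth.csv` (ground truth, for audits only), all UTF-8
#' with ISO-8601 dates and a header row; the configuration is stored as
#' `config.yaml`.
#'
#' @param bundle a `claims_bundle` (with claim rows).
#' @param dir output directory (created if needed).
#' @param validation optional validation table from
#'   [export_validation_sample()]; by default one is drawn with the
#'   bundle's configured validation settings and the bundle seed.
#' @return `dir`, invisibly.
#' @export
write_claims_csv <- function(bundle, dir, validation = NULL) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (is.null(bundle$diagnosis_claims))
    stop("bundle was generated with `claims = FALSE`; no claim rows to ",
         "write", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(validation))
    validation <- export_validation_sample(bundle,
                                           seed = bundle$config$seed)
  w <- function(d, f) write.csv(d, file.path(dir, f), row.names = FALSE)
  w(bundle$persons, "persons.csv")
  w(bundle$diagnosis_claims, "diagnoses.csv")
  w(bundle$prescription_claims, "prescriptions.csv")
  w(validation, "validation.csv")
  w(bundle$hidden_truth, "truth.csv")
  cfg <- bundle$config
  cfg_out <- lapply(unclass(cfg), function(x) {
    if (inherits(x, "Date")) format(x, "%Y-%m-%d")
    else if (is.data.frame(x)) as.list(x)
    else x
  })
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read claims tables written by [write_claims_csv()]
#'
#' @param dir directory containing the CSV files.
#' @param truth include `truth.csv` (default FALSE: the main-study view).
#' @return list with `persons`, `diagnosis_claims`,
#'   `prescription_claims`, `validation` and (optionally) `hidden_truth`;
#'   date columns are parsed to `Date`.
#' @export
read_claims_csv <- function(dir, truth = FALSE) {
  rd <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  persons <- rd("persons.csv")
  persons$exit_date <- as.Date(persons$exit_date)
  dx <- rd("diagnoses.csv"); dx$date <- as.Date(dx$date)
  dx$icd9_code <- as.character(dx$icd9_code)
  rx <- rd("prescriptions.csv"); rx$date <- as.Date(rx$date)
  out <- list(persons = persons, diagnosis_claims = dx,
              prescription_claims = rx,
              validation = rd("validation.csv"))
  if (truth) {
    tr <- rd("truth.csv")
    tr$event_date <- as.Date(tr$event_date)
    out$hidden_truth <- tr
  }
  out
}
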