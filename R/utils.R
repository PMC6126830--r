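# Internal helpers shared across modules.

AGE_BANDS <- c("51-60", "61-70", ">70")

#' Assign study age bands
#'
#' Bands follow the cohort design: 51-60, 61-70, >70 years.  Ages of 50 or
#' below are outside the study population and map to NA.
#'
#' @param age numeric vector of ages in whole years.
#' @return factor with levels `"51-60"`, `"61-70"`, `">70"`.
#' @export
age_band <- function(age) {
  stopifnot(is.numeric(age))
  band <- rep(NA_character_, length(age))
  band[age >= 51 & age <= 60] <- "51-60"
  band[age >= 61 & age <= 70] <- "61-70"
  band[age >= 71] <- ">70"
  factor(band, levels = AGE_BANDS)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed for an independent random stream; kept < 2^31 so it
# is a valid R integer seed.
stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 10007 + stream * 97) %% 2147483629L)
}

# Age at a given date from birth year under the mid-year (July 1) convention:
# claims carry no birth date, so everyone born in year Y turns (year - Y) in
# the middle of the calendar year.
age_at <- function(birth_year, date) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  midyear <- as.Date(paste0(yr, "-07-01"))
  as.integer(ifelse(date >= midyear, yr - birth_year, yr - birth_year - 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop("configuration error: `", name, "` must be a probability in [0, 1]",
         call. = FALSE)
  invisible(x)
}

assert_rate <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
    stop("configuration error: `", name, "` must be a non-negative rate",
         call. = FALSE)
  invisible(x)
}
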