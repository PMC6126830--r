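# Medication-exposure classification rules and the multivariable Cox model.

test_that("three qualifying claims of one class assign that class", {
  rx <- rx_rows(1L, c("2004-02-01", "2004-03-01", "2004-04-01"),
                "SAMA", days = 30L)
  prof <- classify_medication_exposure(rx)
  expect_equal(as.character(prof$inhaled_class), "SAMA")
  expect_false(prof$rescue_use)
  expect_false(prof$excluded_combination)
  expect_equal(prof$qualifying_claims, 3L)
})

test_that("long-acting user with short rescue claims keeps the class", {
  rx <- rbind(
    rx_rows(1L, c("2004-02-01", "2004-03-01", "2004-04-01"),
            "LABA_ICS", days = 28L),
    rx_rows(1L, "2004-03-15", "SABA", days = 7L))
  prof <- classify_medication_exposure(rx)
  expect_equal(as.character(prof$inhaled_class), "LABA_ICS")
  expect_true(prof$rescue_use)
  expect_false(prof$excluded_combination)
})

test_that("two qualifying classes mark a combination exclusion", {
  rx <- rbind(
    rx_rows(1L, c("2004-02-01", "2004-03-01", "2004-04-01"), "SAMA", 30L),
    rx_rows(1L, c("2004-02-10", "2004-03-10", "2004-04-10"), "LABA", 30L))
  prof <- classify_medication_exposure(rx)
  expect_true(prof$excluded_combination)
  expect_equal(as.character(prof$inhaled_class), "none")
})

test_that("short-acting user with a long-acting claim is a combination", {
  # the rescue allowance is one-directional
  rx <- rbind(
    rx_rows(1L, c("2004-02-01", "2004-03-01", "2004-04-01"), "SABA", 30L),
    rx_rows(1L, "2004-03-15", "LAMA", days = 30L))
  prof <- classify_medication_exposure(rx)
  expect_true(prof$excluded_combination)
})

test_that("the duration threshold is strict and per claim", {
  rx14 <- rx_rows(1L, c("2004-02-01", "2004-03-01", "2004-04-01"),
                  "SAMA", days = 14L)
  expect_equal(as.character(classify_medication_exposure(rx14)$inhaled_class),
               "none")
  rx15 <- rx_rows(1L, c("2004-02-01", "2004-03-01", "2004-04-01"),
                  "SAMA", days = 15L)
  expect_equal(as.character(classify_medication_exposure(rx15)$inhaled_class),
               "SAMA")
  # person-level accumulation variant: three 8-day claims sum past 14
  rx8 <- rx_rows(1L, c("2004-02-01", "2004-03-01", "2004-04-01"),
                 "SAMA", days = 8L)
  expect_equal(as.character(
    classify_medication_exposure(rx8, accumulate = TRUE)$inhaled_class),
    "SAMA")
  expect_equal(as.character(
    classify_medication_exposure(rx8)$inhaled_class), "none")
})

test_that("fewer than three qualifying claims fail the stationary rule", {
  rx <- rx_rows(1L, c("2004-02-01", "2004-03-01"), "SAMA", 30L)
  prof <- classify_medication_exposure(rx)
  expect_equal(as.character(prof$inhaled_class), "none")
  expect_equal(prof$qualifying_claims, 2L)
})

test_that("raising the threshold can only shrink the qualifying set", {
  b <- simulate_population(sim_config(n_persons = 4000, seed = 26))
  rx <- b$prescription_claims
  ids <- identify_copd_cohort(b)$person_id
  p14 <- classify_medication_exposure(rx, ids)
  p21 <- classify_medication_exposure(rx, ids, min_days = 21)
  q14 <- p14$person_id[p14$inhaled_class != "none"]
  q21 <- p21$person_id[p21$inhaled_class != "none"]
  expect_true(all(q21 %in% q14))
})

test_that("classification ignores claim row order", {
  rx <- rbind(
    rx_rows(1L, c("2004-02-01", "2004-03-01", "2004-04-01"), "LAMA", 30L),
    rx_rows(1L, "2004-03-15", "SAMA", days = 7L),
    rx_rows(2L, c("2004-02-01", "2004-03-01", "2004-04-01"), "SABA", 20L))
  p1 <- classify_medication_exposure(rx)
  set.seed(2)
  p2 <- classify_medication_exposure(rx[sample.int(nrow(rx)), ])
  expect_equal(p1, p2)
})

test_that("unmapped drug codes warn and land in the unclassified bucket", {
  rx <- rbind(rx_rows(1L, "2004-02-01", "MYSTERY", 30L),
              rx_rows(2L, c("2004-02-01", "2004-03-01", "2004-04-01"),
                      "SAMA", 30L))
  expect_warning(prof <- classify_medication_exposure(rx), "MYSTERY")
  expect_true(prof$unclassified[prof$person_id == 1L])
  expect_false(prof$unclassified[prof$person_id == 2L])
})

test_that("every exposed subject falls in exactly one exposure state", {
  b <- simulate_population(sim_config(n_persons = 8000, seed = 37))
  ids <- identify_copd_cohort(b)$person_id
  prof <- classify_medication_exposure(b$prescription_claims, ids)
  expect_equal(nrow(prof), length(ids))
  state <- ifelse(prof$excluded_combination, "combination",
                  as.character(prof$inhaled_class))
  expect_true(all(state %in% c("combination", "none", "SAMA", "SABA",
                               "LAMA", "LABA", "LABA_ICS")))
  # combination users never simultaneously carry a class
  expect_true(all(prof$inhaled_class[prof$excluded_combination] == "none"))
})

test_that("co-medication flags respect the cutoff date", {
  rx <- rbind(rx_rows(1L, "2004-05-01", "statin", 30L),
              rx_rows(1L, "2007-05-01", "aspirin", 30L))
  cut <- data.frame(person_id = 1L, cutoff_date = as.Date("2005-12-31"))
  prof <- classify_medication_exposure(rx, cutoff = cut)
  expect_true(prof$statin)
  expect_false(prof$aspirin)
})

test_that("medication model emits the full term table in order", {
  b <- simulate_population(sim_config(n_persons = 30000, seed = 55))
  coh <- build_cohort(b, ratio = 1, seed = 2)
  cases <- coh[coh$D == 1, ]
  prof <- classify_medication_exposure(b$prescription_claims,
                                       cases$person_id)
  out <- fit_medication_cox(cases, prof)
  expect_equal(out$table$term,
               c("SAMA", "SABA", "LAMA", "LABA", "LABA plus ICS",
                 "Statin", "Aspirin", "Steroid", "NSAID", "CCI score",
                 "Age (continuous)"))
  expect_gt(out$n_excluded_combination, 0)
  expect_equal(out$n, nrow(cases) - out$n_excluded_combination)
  expect_true(all(out$table$ci_low < out$table$hr &
                    out$table$hr < out$table$ci_high))
})

test_that("zero-variance exposure terms reduce the model to CCI and age", {
  set.seed(4)
  n <- 400
  dat <- data.frame(person_id = 1:n,
                    followup_years = rexp(n, 0.2),
                    event = rbinom(n, 1, 0.3),
                    cci_score = rpois(n, 1),
                    age_years = sample(55:85, n, TRUE))
  prof <- data.frame(person_id = 1:n,
                     inhaled_class = factor("none",
                                            levels = c("none", "SAMA",
                                                       "SABA", "LAMA",
                                                       "LABA", "LABA_ICS")),
                     rescue_use = FALSE, excluded_combination = FALSE,
                     unclassified = FALSE, qualifying_claims = 0L,
                     statin = FALSE, aspirin = FALSE,
                     steroid_oral = FALSE, nsaid = FALSE)
  expect_warning(out <- fit_medication_cox(dat, prof), "no exposed")
  expect_equal(out$table$term, c("CCI score", "Age (continuous)"))
})

test_that("known medication effects are recovered within two standard errors", {
  med <- default_medication_config()
  med$effects[] <- 0
  med$effects[["SABA"]] <- log(1.9)
  med$comed_effects[] <- 0
  med$comed_effects[["statin"]] <- log(0.6)
  cfg <- sim_config(n_persons = 40000, seed = 61,
                    baseline_hazard = 0.006, medication = med)
  b <- simulate_population(cfg)
  cases <- identify_copd_cohort(b)
  cases <- compute_cci(b, cases)
  cases <- compute_followup(cases, b)
  prof <- classify_medication_exposure(b$prescription_claims,
                                       cases$person_id)
  out <- fit_medication_cox(cases, prof)
  cf <- coef(out$fit$fit)
  se <- sqrt(diag(vcov(out$fit$fit)))
  expect_lt(abs(cf[["SABA"]] - log(1.9)), 2 * se[["SABA"]])
  expect_lt(abs(cf[["statin"]] - log(0.6)), 2 * se[["statin"]])
})
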