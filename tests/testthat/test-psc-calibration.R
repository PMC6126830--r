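# Measurement-error regression and the two-stage calibration estimator.

make_validation <- function(n = 400, seed = 3) {
  set.seed(seed)
  d <- data.frame(D = rbinom(n, 1, 0.3))
  d$PS_c <- plogis(-1 + 0.8 * d$D + rnorm(n, 0, 0.5))
  d
}

test_that("identity scores give (0, 0, 1) and an unchanged estimate", {
  v <- make_validation()
  v$PS_m <- v$PS_c
  em <- fit_error_model(v)
  expect_equal(em$gamma0, 0, tolerance = 1e-10)
  expect_equal(em$gamma, 0, tolerance = 1e-10)
  expect_equal(em$gamma_c, 1, tolerance = 1e-10)
  res <- calibrate(0.53, 1.1, em, "standard_rc")
  expect_equal(res$beta_star, 0.53, tolerance = 1e-10)
})

test_that("least squares recovers a known error model (normal-equations oracle)", {
  set.seed(11)
  v <- make_validation(1000, seed = 8)
  v$PS_m <- 0.1 + 0.05 * v$D + 0.8 * v$PS_c + rnorm(1000, 0, 0.01)
  em <- fit_error_model(v)

  X <- cbind(1, v$D, v$PS_c)
  oracle <- solve(t(X) %*% X, t(X) %*% v$PS_m)
  expect_equal(c(em$gamma0, em$gamma, em$gamma_c), as.numeric(oracle),
               tolerance = 1e-10)
  se <- sqrt(diag(vcov(em$fit)))
  expect_lt(abs(em$gamma0 - 0.1), 3 * se[1])
  expect_lt(abs(em$gamma - 0.05), 3 * se[2])
  expect_lt(abs(em$gamma_c - 0.8), 3 * se[3])
})

test_that("error model succeeds at the study's validation sample sizes", {
  b <- simulate_population(sim_config(n_persons = 12000, seed = 19,
                                      claims = FALSE))
  val <- export_validation_sample(b, seed = 4)   # 312 + 804
  psc <- fit_propensity(val, c("age_band", "cci_score"))
  val$PS_c <- psc$scores
  psm <- fit_propensity(val, c("age_band", "cci_score", "smoking",
                               "alcohol", "bmi"),
                        variant = "gold_standard")
  val$PS_m <- psm$scores
  em <- fit_error_model(val)
  expect_equal(em$n_validation, 1116L)
  expect_gt(em$gamma_c, 0)
})

test_that("error-model input validation", {
  v <- make_validation(10)
  expect_error(fit_error_model(v), "lacks column")
  v$PS_m <- v$PS_c
  expect_error(fit_error_model(v[1:2, ]), "too small")
  v$PS_c <- 0.5   # constant within D groups -> collinear with intercept
  expect_error(fit_error_model(v), "collinear")
})

test_that("calibration arithmetic follows both formula modes", {
  em <- structure(list(gamma0 = 0, gamma = 0.05, gamma_c = 0.8,
                       sigma2 = 0, n_validation = 100),
                  class = "error_model_fit")
  std <- calibrate(0.6, 1.2, em, "standard_rc")
  expect_equal(std$beta_star, 0.6 - 1.2 * 0.05 / 0.8)   # 0.525
  lit <- calibrate(0.6, 1.2, em, "paper_literal")
  expect_equal(lit$beta_star, 0.6 - 1.2 * 0.8 * 0.05)
  expect_equal(std$hr_star, exp(std$beta_star))

  # gamma = 0: no differential missingness, estimate unchanged in any mode
  em0 <- structure(list(gamma0 = 0.1, gamma = 0, gamma_c = 0.7),
                   class = "error_model_fit")
  expect_equal(calibrate(0.6, 1.2, em0, "standard_rc")$beta_star, 0.6)
  expect_equal(calibrate(0.6, 1.2, em0, "paper_literal")$beta_star, 0.6)

  # the two modes agree exactly when gamma_c = 1
  em1 <- structure(list(gamma0 = 0, gamma = 0.07, gamma_c = 1),
                   class = "error_model_fit")
  expect_equal(calibrate(0.5, 0.9, em1, "standard_rc")$beta_star,
               calibrate(0.5, 0.9, em1, "paper_literal")$beta_star)

  # near-zero gamma_c is unidentified in standard mode only
  emz <- structure(list(gamma0 = 0, gamma = 0.05, gamma_c = 1e-9),
                   class = "error_model_fit")
  expect_error(calibrate(0.6, 1.2, emz, "standard_rc"), "unidentified")
  expect_silent(calibrate(0.6, 1.2, emz, "paper_literal"))
})

test_that("calibrated estimate is invariant to affine rescaling of PS_c", {
  b <- simulate_population(recovery_config(8000, seed = 2))
  main <- cohort_from_truth(b)
  val <- export_validation_sample(b, fraction = 0.25, seed = 5)

  run_scaled <- function(a, s) {
    ps <- fit_propensity(main, c("age_band", "cci_score"))
    main$PS <- a + s * ps$scores
    adj <- fit_cox(main, c("D", "PS"))
    psc <- fit_propensity(val, c("age_band", "cci_score"))
    val$PS_c <- a + s * psc$scores
    psm <- fit_propensity(val, c("age_band", "cci_score", "smoking",
                                 "alcohol", "bmi"),
                          variant = "gold_standard")
    val$PS_m <- psm$scores
    em <- fit_error_model(val)
    calibrate(unname(coef(adj$fit)["D"]), unname(coef(adj$fit)["PS"]),
              em)$beta_star
  }
  expect_equal(run_scaled(0, 1), run_scaled(0.3, 2.5), tolerance = 1e-6)
})

test_that("two-stage runner validates schemas and is deterministic", {
  b <- simulate_population(recovery_config(6000, seed = 9))
  main <- cohort_from_truth(b)
  val <- export_validation_sample(b, fraction = 0.25, seed = 2)

  r1 <- run_two_stage(main, val)
  r2 <- run_two_stage(main, val)
  expect_identical(r1[c("beta_hat", "beta_star", "gamma", "gamma_c")],
                   r2[c("beta_hat", "beta_star", "gamma", "gamma_c")])

  leaky <- main
  leaky$smoking <- 0L
  expect_error(run_two_stage(leaky, val), "must not contain")
  expect_error(run_two_stage(main, val[, setdiff(names(val), "bmi")]),
               "lacks column")
  expect_error(run_two_stage(main[, setdiff(names(main), "cci_score")],
                             val),
               "lacks column")
})

test_that("uninformative confounders leave the adjusted estimate unchanged", {
  b <- simulate_population(recovery_config(20000, seed = 15))
  main <- cohort_from_truth(b)
  val <- export_validation_sample(b, fraction = 0.3, seed = 3)
  # replace the confounders with pure noise, unrelated to D and outcome
  set.seed(8)
  val$smoking <- rbinom(nrow(val), 1, 0.5)
  val$alcohol <- rbinom(nrow(val), 1, 0.4)
  val$bmi <- rnorm(nrow(val), 24, 3)
  res <- run_two_stage(main, val)
  expect_lt(abs(res$beta_star - res$beta_hat), 0.05)
})

test_that("calibration removes most hidden-confounder bias (small replicate set)", {
  # deeper 200-replicate version lives in the acceptance suite
  out <- psc_parameter_recovery(n_reps = 12, n_persons = 10000, seed = 21)
  expect_lt(abs(out$mean_beta_star - 0.48),
            abs(out$mean_beta_hat - 0.48))
  expect_gt(out$mean_beta_hat - 0.48, 0.05)   # bias is really there
})
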