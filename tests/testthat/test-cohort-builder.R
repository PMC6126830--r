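# Entry criteria, Charlson index, matching and follow-up derivation,
# hand-traced on small fixtures.

test_that("a fully qualifying person is included with index at first treated visit", {
  coh <- identify_copd_cohort(qualifying_case_claims())
  expect_equal(nrow(coh), 1L)
  expect_equal(coh$person_id, 1L)
  expect_equal(coh$index_date, as.Date("2004-02-01"))
  expect_equal(coh$age_years, 71L)      # born 1932, index before July 1
  expect_equal(as.character(coh$age_band), ">70")
})

test_that("a washout violation excludes the person", {
  cl <- qualifying_case_claims()
  cl$prescription_claims <- rbind(cl$prescription_claims,
                                  rx_rows(1L, "2003-09-15"))
  expect_equal(nrow(identify_copd_cohort(cl)), 0L)
})

test_that("age 50 at index is excluded ('older than 50' read strictly)", {
  cl <- qualifying_case_claims()
  cl$persons$birth_year <- 1953L   # age 50 on 2004-02-01
  expect_equal(nrow(identify_copd_cohort(cl)), 0L)
  cl$persons$birth_year <- 1952L   # age 51
  expect_equal(nrow(identify_copd_cohort(cl)), 1L)
})

test_that("insufficient diagnoses, claims, wrong sex or prior outcome exclude", {
  cl <- qualifying_case_claims()
  cl$diagnosis_claims <- dx_rows(1L, "2004-02-01", "491")   # one dx date
  expect_equal(nrow(identify_copd_cohort(cl)), 0L)

  cl <- qualifying_case_claims()
  cl$prescription_claims <- cl$prescription_claims[1:2, ]   # two rx claims
  expect_equal(nrow(identify_copd_cohort(cl)), 0L)

  cl <- qualifying_case_claims()
  cl$persons$sex <- "F"
  expect_equal(nrow(identify_copd_cohort(cl)), 0L)

  cl <- qualifying_case_claims()
  cl$diagnosis_claims <- rbind(cl$diagnosis_claims,
                               dx_rows(1L, "2003-05-01", "185"))
  expect_equal(nrow(identify_copd_cohort(cl)), 0L)
})

test_that("empty claims give an empty cohort and malformed dates a parse error", {
  cl <- fixture_claims(fixture_persons(integer(0)),
                       dx_rows(integer(0), character(0), character(0)),
                       rx_rows(integer(0), character(0)))
  expect_equal(nrow(identify_copd_cohort(cl)), 0L)

  bad <- qualifying_case_claims()
  bad$diagnosis_claims$date <- c("2004-02-01", "not-a-date")
  expect_error(identify_copd_cohort(bad), "parse error.*row")
})

test_that("criteria application is idempotent", {
  b <- simulate_population(sim_config(n_persons = 3000, seed = 12))
  c1 <- identify_copd_cohort(b)
  # restrict claims to the identified persons and re-apply
  main <- export_main_study(b)
  main$persons <- main$persons[main$persons$person_id %in% c1$person_id, ]
  c2 <- identify_copd_cohort(main)
  expect_equal(c1, c2)
})

test_that("Charlson index: empty, single-condition and weighted cases", {
  cl <- qualifying_case_claims()
  coh <- identify_copd_cohort(cl)
  scored <- compute_cci(cl, coh)
  expect_equal(scored$cci_score, 0)
  expect_false(any(as.logical(scored[default_comorbidity_table()$condition])))

  cl$diagnosis_claims <- rbind(cl$diagnosis_claims,
                               dx_rows(1L, "2003-03-01", "410"))
  expect_equal(compute_cci(cl, coh)$cci_score, 1)

  # claim after index does not count
  cl2 <- qualifying_case_claims()
  cl2$diagnosis_claims <- rbind(cl2$diagnosis_claims,
                                dx_rows(1L, "2004-06-01", "410"))
  expect_equal(compute_cci(cl2, coh)$cci_score, 0)

  # classic weights: metastatic carcinoma scores 6
  cl3 <- qualifying_case_claims()
  cl3$diagnosis_claims <- rbind(cl3$diagnosis_claims,
                                dx_rows(1L, "2003-03-01", "196"))
  expect_equal(compute_cci(cl3, coh,
                           default_cci_map("charlson"))$cci_score, 6)
  expect_equal(compute_cci(cl3, coh)$cci_score, 1)

  bad_map <- default_cci_map()
  bad_map$weight[1] <- NA
  expect_error(compute_cci(cl3, coh, bad_map), "configuration error")
})

test_that("simulated exposed cohort mean CCI is near 1.7", {
  b <- simulate_population(sim_config(n_persons = 40000, seed = 21))
  cases <- identify_copd_cohort(b)
  scored <- compute_cci(b, cases)
  expect_lt(abs(mean(scored$cci_score) - 1.7),
            3 * 1.5 / sqrt(nrow(scored)))
})

test_that("matching draws ratio controls per case with matching band", {
  b <- simulate_population(sim_config(n_persons = 8000, seed = 33))
  cases <- identify_copd_cohort(b)
  ctrl <- match_controls(cases, b, ratio = 3, seed = 9)
  expect_equal(nrow(ctrl), 3L * nrow(cases))
  expect_false(any(duplicated(ctrl$person_id)))
  expect_false(any(ctrl$person_id %in% cases$person_id))
  expect_equal(as.character(ctrl$age_band),
               as.character(cases$age_band[match(ctrl$matched_case,
                                                 cases$person_id)]))
  expect_equal(ctrl$index_date,
               cases$index_date[match(ctrl$matched_case, cases$person_id)])
})

test_that("matching is deterministic and invariant to pool row order", {
  b <- simulate_population(sim_config(n_persons = 4000, seed = 14))
  cases <- identify_copd_cohort(b)
  c1 <- match_controls(cases, b, ratio = 2, seed = 5)
  c2 <- match_controls(cases, b, ratio = 2, seed = 5)
  expect_identical(c1, c2)

  shuffled <- export_main_study(b)
  set.seed(1)
  shuffled$persons <- shuffled$persons[sample.int(nrow(shuffled$persons)), ]
  c3 <- match_controls(cases, shuffled, ratio = 2, seed = 5)
  expect_setequal(c3$person_id, c1$person_id)
})

test_that("zero cases give zero controls; exhaustion errors name the stratum", {
  b <- simulate_population(sim_config(n_persons = 2000, seed = 2))
  cases <- identify_copd_cohort(b)
  expect_equal(nrow(match_controls(cases[0, ], b, ratio = 3, seed = 1)), 0L)
  expect_error(match_controls(cases, b, ratio = 500, seed = 1),
               "stratum.*shortfall|shortfall")
})

test_that("small-stratum matching selects all eligible controls exactly once", {
  # 2 cases in band >70, pool of exactly 6 eligible -> all 6 selected
  persons <- fixture_persons(1:8)
  dx <- rbind(dx_rows(1L, c("2004-02-01", "2004-03-01"), "491"),
              dx_rows(2L, c("2004-02-05", "2004-03-05"), "492"))
  rx <- rbind(rx_rows(1L, c("2004-02-01", "2004-03-01", "2004-04-01")),
              rx_rows(2L, c("2004-02-05", "2004-03-05", "2004-04-05")))
  cl <- fixture_claims(persons, dx, rx)
  cases <- identify_copd_cohort(cl)
  expect_equal(nrow(cases), 2L)
  ctrl <- match_controls(cases, cl, ratio = 3, seed = 11)
  expect_setequal(ctrl$person_id, 3:8)
  expect_false(any(duplicated(ctrl$person_id)))
})

test_that("follow-up handles full follow-up, events and early censoring", {
  persons <- fixture_persons(1:3)
  persons$exit_date[3] <- as.Date("2005-01-01")
  coh <- data.frame(person_id = 1:3,
                    index_date = as.Date(c("2004-01-01", "2004-07-01",
                                           "2004-01-01")))
  dx <- rbind(dx_rows(2L, "2006-07-01", "185"),
              dx_rows(3L, "2006-01-01", "185"))
  cl <- fixture_claims(persons, dx, rx_rows(integer(0), character(0)))
  out <- compute_followup(coh, cl)
  expect_equal(out$followup_years[1], 5.0, tolerance = 2 / 365.25)
  expect_equal(out$event[1], 0L)
  expect_equal(out$censor_reason[1], "admin_end")

  expect_equal(out$followup_years[2], 2.0, tolerance = 2 / 365.25)
  expect_equal(out$event[2], 1L)
  expect_equal(out$censor_reason[2], "event")

  # withdrawal on 2005-01-01 precedes the 2006 outcome claim
  expect_equal(out$followup_years[3], 1.0, tolerance = 2 / 365.25)
  expect_equal(out$event[3], 0L)
  expect_equal(out$censor_reason[3], "death_or_withdrawal")
})

test_that("an outcome claim before index raises a data-consistency error", {
  persons <- fixture_persons(1L)
  coh <- data.frame(person_id = 1L, index_date = as.Date("2004-06-01"))
  cl <- fixture_claims(persons, dx_rows(1L, "2004-01-15", "185"),
                       rx_rows(integer(0), character(0)))
  expect_error(compute_followup(coh, cl), "data-consistency")
})

test_that("person-time accounting is exact over the built cohort", {
  b <- simulate_population(sim_config(n_persons = 5000, seed = 44))
  coh <- build_cohort(b, ratio = 2, seed = 3)
  expect_true(all(coh$followup_years > 0))
  expect_true(all(coh$event %in% 0:1))
  expect_true(all(coh$censor_reason[coh$event == 1] == "event"))
  py <- sum(coh$followup_years)
  rate <- incidence_rate(sum(coh$event), py)
  expect_equal(rate, sum(coh$event) / py * 1e5)
  agg <- sum(tapply(coh$followup_years, coh$D, sum))
  expect_equal(agg, py)
})
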