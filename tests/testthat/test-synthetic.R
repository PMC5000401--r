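test_that("generation is deterministic under (params, seed)", {
  p <- activity_gen_params(n_days = 2)
  a <- generate_epoch_traces(p, 3, seed = 7)
  b <- generate_epoch_traces(p, 3, seed = 7)
  expect_identical(a, b)
  expect_identical(generate_covariates(50, seed = 9),
                   generate_covariates(50, seed = 9))
  cov <- generate_covariates(50, seed = 9)
  summ <- generate_activity_summaries(cov, seed = 10)
  prim <- data.frame(participant_id = cov$participant_id,
                     quartile = rep(1:4, length.out = 50))
  expect_identical(
    generate_outcomes(prim, cov, outcome_gen_params(), seed = 11),
    generate_outcomes(prim, cov, outcome_gen_params(), seed = 11))
})

test_that("generator parameters are validated", {
  expect_error(activity_gen_params(wear_start_hour = 8, wear_end_hour = 17),
               "10 hours")
  expect_error(activity_gen_params(sedentary_met_range = c(0.5, 1.5)),
               "thresholds")
  expect_error(generate_epoch_traces(activity_gen_params(), 0, seed = 1),
               ">= 1")
  expect_error(generate_covariates(0, seed = 1), ">= 1")
  expect_error(outcome_gen_params(baseline_hazard_per_year = -1))
})

test_that("a full-wear generated day recovers the designed wear window", {
  p <- activity_gen_params(p_midday_nonwear = 0, n_days = 2)
  tr <- generate_epoch_traces(p, 5, seed = 13)
  daily <- process_epochs(tr, cutoffs = 30)
  expect_true(all(daily$wear_min == 840))
  expect_true(all(daily$is_valid))
})

test_that("detected sedentary bout lengths track the generator mean", {
  # truncation at window edges and the ceiling-to-whole-minutes rule shift
  # the detected mean only slightly at mean 40
  p <- activity_gen_params(sedentary_bout_mean_min = 40,
                           between_participant_sd = 0,
                           p_midday_nonwear = 0, n_days = 10)
  tr <- generate_epoch_traces(p, 50, seed = 17)   # 500 participant-days
  lens <- numeric(0)
  for (pid in unique(tr$participant_id)) {
    for (d in unique(tr$date)) {
      met <- tr$met[tr$participant_id == pid & tr$date == d]
      lens <- c(lens, detect_sedentary_bouts(met)$length)
    }
  }
  expect_lt(abs(mean(lens) - 40) / 40, 0.10)
})

test_that("covariate marginals behave as configured", {
  cov <- generate_covariates(430, seed = 19)
  expect_true(all(cov$age >= 40 & cov$age <= 64))
  expect_true(all(cov$income %in% c("<4M", "4-8M", ">=8M")))
  big <- generate_covariates(10000, seed = 23)
  p_hat <- mean(big$sex == "female")
  se <- sqrt(0.125 * 0.875 / 10000)
  expect_lt(abs(p_hat - 0.125), 3 * se)
})

test_that("component counts round-trip through biomarker construction", {
  set.seed(29)
  for (target in 0:5) {
    for (i in 1:50) {
      sex <- sample(c("male", "female"), 1)
      p <- biomarkers_from_status(target, sex)
      st <- classify_components(p)
      expect_equal(st$count, target)
      expect_equal(classify_mets(st), target >= 3)
    }
  }
  # target 0: every flag false
  st <- classify_components(biomarkers_from_status(0, "female", seed = 1))
  expect_false(any(unlist(st[1, 1:5])))
  expect_error(biomarkers_from_status(6, "male"), "0..5")
})

test_that("baseline panels are always MetS-negative and onset is absorbing", {
  cov <- generate_covariates(300, seed = 31)
  prim <- data.frame(participant_id = cov$participant_id,
                     quartile = rep(1:4, length.out = 300))
  visits <- generate_outcomes(prim, cov, outcome_gen_params(), seed = 37)
  visits <- visits[order(visits$participant_id, visits$exam_date), ]
  st <- classify_components(visits)
  mets <- classify_mets(st)
  baseline <- !duplicated(visits$participant_id)
  expect_false(any(mets[baseline]))
  # visits stop at the first positive exam: positivity only at the last visit
  last <- !duplicated(visits$participant_id, fromLast = TRUE)
  expect_false(any(mets & !last))
})

test_that("mismatched participant sets are rejected", {
  cov <- generate_covariates(10, seed = 41)
  prim <- data.frame(participant_id = c("X1", "X2"), quartile = c(1, 2))
  expect_error(generate_outcomes(prim, cov, outcome_gen_params()),
               "different participants")
})

test_that("cumulative incidence tracks the design scale", {
  # null quartile effects so incidence is set by the baseline hazard alone;
  # design scale is ~19% over 3 years (83/430)
  cov <- generate_covariates(4000, seed = 43)
  prim <- data.frame(participant_id = cov$participant_id,
                     quartile = rep(1:4, 1000))
  pars <- outcome_gen_params(true_log_hr_by_quartile = c(0, 0, 0),
                             baseline_hazard_per_year = -log(1 - 0.19) / 3)
  visits <- generate_outcomes(prim, cov, pars, seed = 47)
  rec <- build_survival_records(visits, cov,
                                cbind(prim, variable = "prolonged",
                                      cutoff = 30))
  p_hat <- mean(rec$event)
  expect_lt(abs(p_hat - 0.19), qnorm(0.995) * sqrt(0.19 * 0.81 / 4000))
  # and the null generator leaves quartile incidences equal within 3 SE
  q <- rec$quartile_prolonged_30
  inc <- tapply(rec$event, q, mean)
  se_diff <- sqrt(2 * 0.19 * 0.81 / 1000)
  expect_true(all(abs(inc - mean(inc)) < 3 * se_diff))
})
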