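normal_panel <- function(sex = "male") {
  data.frame(sex = sex, waist_cm = if (sex == "male") 80 else 75,
             sbp_mmHg = 118, dbp_mmHg = 75, glucose_mmol_per_L = 5.0,
             hdl_mmol_per_L = if (sex == "male") 1.4 else 1.6,
             tg_mmol_per_L = 1.2, on_antihypertensive = FALSE,
             on_hypoglycemic = FALSE, on_lipid_lowering = FALSE,
             stringsAsFactors = FALSE)
}

test_that("components classify per the JIS-2009 thresholds", {
  p <- normal_panel("male")
  p$waist_cm <- 92; p$sbp_mmHg <- 135; p$sbp_mmHg <- 135
  p$glucose_mmol_per_L <- 5.8; p$hdl_mmol_per_L <- 1.2
  p$tg_mmol_per_L <- 1.5
  st <- classify_components(p)
  expect_true(st$central_obesity && st$elevated_bp && st$elevated_glucose)
  expect_false(st$low_hdl || st$high_tg)
  expect_equal(st$count, 3L)
  expect_true(classify_mets(st))
  # waist boundary is >= : 84.9 in a woman is not central obesity
  p <- normal_panel("female"); p$waist_cm <- 84.9
  expect_false(classify_components(p)$central_obesity)
  p$waist_cm <- 85
  expect_true(classify_components(p)$central_obesity)
  # medication flags force their components
  p <- normal_panel("male"); p$tg_mmol_per_L <- 1.0
  p$on_lipid_lowering <- TRUE
  expect_true(classify_components(p)$high_tg)
})

test_that("sex-specific thresholds apply to waist and HDL", {
  m <- normal_panel("male"); f <- normal_panel("female")
  m$waist_cm <- f$waist_cm <- 87
  expect_false(classify_components(m)$central_obesity)
  expect_true(classify_components(f)$central_obesity)
  m <- normal_panel("male"); f <- normal_panel("female")
  m$hdl_mmol_per_L <- f$hdl_mmol_per_L <- 1.1
  expect_false(classify_components(m)$low_hdl)
  expect_true(classify_components(f)$low_hdl)
})

test_that("all 32 component patterns classify by the >= 3 rule", {
  for (sex in c("male", "female")) {
    male <- sex == "male"
    for (bits in 0:31) {
      flags <- as.logical(bitwAnd(bits, 2^(0:4)))
      p <- normal_panel(sex)
      if (flags[1]) p$waist_cm <- if (male) 95 else 90
      if (flags[2]) p$sbp_mmHg <- 140
      if (flags[3]) p$glucose_mmol_per_L <- 6.2
      if (flags[4]) p$hdl_mmol_per_L <- if (male) 0.8 else 1.1
      if (flags[5]) p$tg_mmol_per_L <- 2.1
      st <- classify_components(p)
      expect_equal(st$count, sum(flags))
      expect_equal(unlist(st[1, 1:5], use.names = FALSE), flags)
      expect_equal(classify_mets(st), sum(flags) >= 3)
    }
  }
})

test_that("missing biomarkers need a covering medication flag", {
  p <- normal_panel("male"); p$glucose_mmol_per_L <- NA
  expect_error(classify_components(p), "missing fasting glucose")
  p$on_hypoglycemic <- TRUE
  expect_true(classify_components(p)$elevated_glucose)
  p <- normal_panel("male"); p$waist_cm <- NA
  expect_error(classify_components(p), "waist")
})

test_that("worsening one biomarker never removes a positive diagnosis", {
  set.seed(21)
  for (i in 1:50) {
    p <- biomarkers_from_status(sample(3:5, 1), sample(c("male", "female"), 1))
    stopifnot(classify_mets(classify_components(p)))
    worse <- p
    j <- sample(6, 1)
    worse[[c("waist_cm", "sbp_mmHg", "dbp_mmHg", "glucose_mmol_per_L",
             "hdl_mmol_per_L", "tg_mmol_per_L")[j]]] <-
      c(120, 180, 110, 9, 0.4, 5)[j]
    expect_true(classify_mets(classify_components(worse)))
  }
})

make_visits <- function(pid, dates, counts, sex = "male") {
  rows <- lapply(seq_along(dates), function(i) {
    cbind(data.frame(participant_id = pid,
                     exam_date = as.Date(dates[i]), stringsAsFactors = FALSE),
          biomarkers_from_status(counts[i], sex))
  })
  do.call(rbind, rows)
}

base_cov <- function(pids) {
  data.frame(participant_id = pids, sex = "male", age = 50,
             education = "college+", smoker = "no", income = "4-8M",
             stringsAsFactors = FALSE)
}

test_that("person-time runs from baseline to first positive or last exam", {
  set.seed(31)
  v <- rbind(
    make_visits("A", c("2010-01-15", "2011-01-20", "2012-01-18",
                       "2013-02-10"), c(1, 2, 1, 4)),
    make_visits("B", c("2010-01-15", "2011-03-01", "2014-03-01"),
                c(0, 1, 2)),
    make_visits("C", c("2010-02-01", "2011-02-01"), c(5, 5)),
    make_visits("D", c("2010-02-01"), c(1))
  )
  rec <- build_survival_records(v, base_cov(c("A", "B", "C", "D")))
  expect_equal(sort(rec$participant_id), c("A", "B"))
  a <- rec[rec$participant_id == "A", ]
  expect_equal(a$event, 1L)
  expect_equal(a$time_days, 1122)
  b <- rec[rec$participant_id == "B", ]
  expect_equal(b$event, 0L)
  expect_equal(b$time_days,
               as.numeric(as.Date("2014-03-01") - as.Date("2010-01-15")))
  excl <- attr(rec, "exclusions")
  expect_equal(unname(excl["baseline_mets"]), 1L)   # C positive at baseline
  expect_equal(unname(excl["no_followup"]), 1L)     # D has no second visit
})

test_that("a skipped exam followed by a positive one is an event then", {
  set.seed(32)
  v <- make_visits("E", c("2010-01-01", "2011-01-01", "2013-01-01"),
                   c(0, 1, 3))
  rec <- build_survival_records(v, base_cov("E"))
  expect_equal(rec$event, 1L)
  expect_equal(rec$time_days,
               as.numeric(as.Date("2013-01-01") - as.Date("2010-01-01")))
})

test_that("duplicate exam dates are rejected", {
  set.seed(33)
  v <- make_visits("F", c("2010-01-01", "2010-01-01"), c(0, 0))
  expect_error(build_survival_records(v, base_cov("F")), "duplicate")
})

test_that("incidence rates are per 1000 person-years and conserved", {
  rec <- data.frame(event = c(rep(1, 20), rep(0, 10)),
                    time_years = c(rep(10, 20), rep(14.3, 10)))
  expect_equal(incidence_rate(rec), 1000 * 20 / 343, tolerance = 1e-12)
  expect_equal(round(incidence_rate(rec), 2), 58.31)
  expect_equal(incidence_rate(data.frame(event = 0, time_years = 2)), 0)
  # person-time-weighted average of group rates equals the pooled rate
  set.seed(34)
  rec <- data.frame(event = rbinom(100, 1, 0.3),
                    time_years = runif(100, 1, 4))
  g <- sample(1:3, 100, replace = TRUE)
  by_g <- incidence_rate(rec, by = g)
  pooled <- sum(by_g$rate_per_1000py * by_g$person_years) /
    sum(by_g$person_years)
  expect_equal(pooled, incidence_rate(rec), tolerance = 1e-12)
})
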