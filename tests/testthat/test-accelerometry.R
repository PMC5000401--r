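day <- function(...) {
  # build a 1440-min trace from (value, length) pairs, padded with 2.0 METs
  segs <- list(...)
  met <- numeric(0)
  for (s in segs) met <- c(met, rep(s[1], s[2]))
  stopifnot(length(met) <= 1440)
  c(met, rep(2.0, 1440 - length(met)))
}

test_that("non-wear windows follow the 60-min rule with the 2-min allowance", {
  # plain 70-min sub-1.0 run
  w <- detect_nonwear(day(c(0.8, 70)))
  expect_equal(w$span, 70)
  expect_equal(w$start, 0)
  # interior run of two 1.0-MET minutes is absorbed
  w <- detect_nonwear(day(c(0.8, 30), c(1.0, 2), c(0.8, 40)))
  expect_equal(w$span, 72)
  # a single epoch above 1.0 splits; neither side reaches 60
  expect_equal(nrow(detect_nonwear(day(c(0.8, 30), c(1.2, 1), c(0.8, 40)))),
               0)
  # three consecutive 1.0 minutes terminate
  w <- detect_nonwear(day(c(0.8, 60), c(1.0, 3), c(0.8, 60)))
  expect_equal(w$span, c(60, 60))
  # windows start and end on sub-1.0 epochs: terminal 1.0s are shed
  w <- detect_nonwear(day(c(1.0, 2), c(0.8, 60), c(1.0, 2)))
  expect_equal(c(w$start, w$end), c(2, 62))
  # missing minutes count as sub-1.0
  met <- day(c(0.8, 20)); met[21:80] <- NA
  s <- epoch_series("P1", "2010-04-01", which(!is.na(met)) - 1,
                    met[!is.na(met)])
  expect_equal(detect_nonwear(s)$span, 80)
})

test_that("allowance runs separated by a single sub-1.0 epoch each count", {
  # 1.0,1.0,0.8,1.0,1.0 inside a window: each 1.0-run is <= 2 consecutive
  w <- detect_nonwear(day(c(0.8, 30), c(1.0, 2), c(0.8, 1), c(1.0, 2),
                          c(0.8, 40)))
  expect_equal(w$span, 75)
})

test_that("wear minutes count recorded epochs outside non-wear windows", {
  met <- day(c(0.8, 70))
  expect_equal(wear_minutes(met), 1370)
  # all minutes missing
  s <- epoch_series("P1", "2010-04-01", integer(0), numeric(0))
  expect_equal(wear_minutes(s), 0)
  # overlapping windows are rejected
  expect_error(
    wear_minutes(met, data.frame(start = c(0, 30), end = c(60, 90))),
    "overlap")
})

test_that("sedentary bouts are maximal uninterrupted runs at <= 1.5 METs", {
  b <- detect_sedentary_bouts(day(c(1.2, 35)))
  expect_equal(b$length, 35)
  # one epoch above 1.5 splits a run
  b <- detect_sedentary_bouts(day(c(1.2, 10), c(1.6, 1), c(1.2, 10)))
  expect_equal(b$length, c(10, 10))
  # worn sub-1.0 epochs outside qualifying windows count as sedentary
  b <- detect_sedentary_bouts(day(c(0.8, 30), c(1.2, 10)))
  expect_equal(b$length, 40)
})

test_that("MVPA periods honor span, terminal-epoch and allowance rules", {
  p <- detect_mvpa_periods(day(c(3.5, 12)))
  expect_equal(c(p$span, p$credited), c(12, 12))
  # exactly consumes the 2-min allowance
  p <- detect_mvpa_periods(day(c(3.5, 5), c(2.0, 2), c(3.5, 5)))
  expect_equal(c(p$span, p$credited), c(12, 10))
  # budget exceeded and pure runs too short
  expect_equal(nrow(detect_mvpa_periods(day(c(3.5, 5), c(2.0, 3),
                                            c(3.5, 5)))), 0)
  # 9 minutes is below the minimum duration
  expect_equal(nrow(detect_mvpa_periods(day(c(3.5, 9)))), 0)
  # allowance is cumulative across interruptions within one period
  p <- detect_mvpa_periods(day(c(3.5, 5), c(2.0, 1), c(3.5, 2), c(2.0, 1),
                               c(3.5, 5)))
  expect_equal(c(p$span, p$credited), c(14, 12))
})

test_that("bout accumulation splits exactly at the cut-off", {
  bouts <- data.frame(length = c(35, 30, 10, 5))
  expect_equal(unname(accumulate_bout_time(bouts, 30)), c(65, 15, 80))
  expect_equal(unname(accumulate_bout_time(bouts, 10)), c(75, 5, 80))
  expect_equal(unname(accumulate_bout_time(bouts[0, , drop = FALSE], 30)),
               c(0, 0, 0))
  expect_error(accumulate_bout_time(bouts, 0), "positive")
})

test_that("daily summary composes the detectors", {
  # one 35-min and one 10-min sedentary bout on an otherwise active day
  met <- day(c(1.2, 35), c(2.0, 5), c(1.2, 10))
  d <- summarize_day(epoch_series("P1", "2010-04-01", 0:1439, met))
  expect_equal(d$total_sed_min, 45)
  expect_equal(d$prolonged_sed_30, 35)
  expect_equal(d$nonprolonged_sed_30, 10)
  expect_true(d$is_valid)
})

test_that("participant summaries average valid days only", {
  mk_day <- function(wear, mvpa = 10) {
    data.frame(participant_id = "P1", date = as.Date("2010-04-01"),
               wear_min = wear, total_sed_min = 100,
               prolonged_sed_30 = 60, nonprolonged_sed_30 = 40,
               mvpa_credited_min = mvpa, is_valid = wear >= 600)
  }
  # three valid days: excluded
  p <- summarize_participant(do.call(rbind, rep(list(mk_day(700)), 3)))
  expect_false(p$included)
  # five identical valid days, daily MVPA 10 -> weekly 70
  p <- summarize_participant(do.call(rbind, rep(list(mk_day(700)), 5)))
  expect_true(p$included)
  expect_equal(p$mvpa_min_per_week, 70)
  # invalid days provably ignored
  days <- rbind(mk_day(700, 10), mk_day(650, 20), mk_day(800, 30),
                mk_day(610, 40), mk_day(599, 999), mk_day(0, 999))
  with_invalid <- summarize_participant(days)
  without <- summarize_participant(days[days$is_valid, ])
  expect_equal(with_invalid$mvpa_min_per_week, without$mvpa_min_per_week)
  expect_equal(with_invalid$mean_wear_min, without$mean_wear_min)
})

test_that("detectors agree with enumeration oracles on random traces", {
  set.seed(101)
  for (i in 1:300) {
    met <- random_trace()
    nw <- detect_nonwear(met)
    expect_identical(nw, oracle_nonwear(met))
    expect_identical(detect_sedentary_bouts(met, nw),
                     oracle_sedentary(met, nw))
    expect_identical(detect_mvpa_periods(met, nw), oracle_mvpa(met, nw))
  }
})

test_that("wear, non-wear and missing minutes partition the day", {
  set.seed(202)
  for (i in 1:100) {
    met <- random_trace()
    nw <- detect_nonwear(met)
    mask <- rep(FALSE, 1440)
    for (j in seq_len(nrow(nw))) mask[(nw$start[j] + 1):nw$end[j]] <- TRUE
    expect_equal(wear_minutes(met, nw) + sum(nw$span) +
                   sum(is.na(met) & !mask), 1440)
  }
})
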