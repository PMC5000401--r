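# Synthetic cohort generator: epoch traces with an alternating-renewal bout
# structure, baseline covariates patterned on the study population, and
# visit-level biomarker panels whose metabolic-syndrome onset follows a
# proportional-hazards model on the prolonged-sedentary-time quartile.

#' Activity-trace generator parameters
#'
#' Defaults emulate office workers wearing the device during waking hours for
#' 10 consecutive days: a 07:00--21:00 wear window (840 min/day), sedentary
#' bouts with a right-skewed log-normal length distribution (mean 15 min)
#' alternating with shorter active bouts, about 5% of active bouts at MVPA
#' intensity (landing near ~50 credited MVPA min/week), and an occasional
#' midday non-wear gap. Minutes outside the wear window carry sub-1.0-MET
#' values, which is what the non-wear detector keys on. The default
#' sedentary MET range starts at 1.0 so that sub-1.0 values are reserved for
#' the non-wear signal and detection recovers the designed wear window
#' exactly.
#'
#' @param sedentary_bout_mean_min mean sedentary bout length (minutes).
#' @param sedentary_bout_sigma log-scale SD of sedentary bout lengths.
#' @param active_bout_mean_min mean active bout length (minutes).
#' @param active_bout_sigma log-scale SD of active bout lengths.
#' @param p_mvpa_given_active probability an active bout is MVPA-level.
#' @param sedentary_met_range,light_met_range,mvpa_met_range MET intervals
#'   used to draw minute intensities for each bout type.
#' @param wear_start_hour,wear_end_hour daily wear window (clock hours).
#' @param p_midday_nonwear probability a day contains a midday non-wear gap.
#' @param midday_nonwear_mean_min mean length of that gap (minutes, >= 60 so
#'   it is detectable).
#' @param n_days measurement days per participant.
#' @param between_participant_sd log-scale SD of a participant-level
#'   multiplier on the sedentary bout mean (gives participants stably
#'   different accumulation patterns).
#' @return validated parameter list of class `activity_gen_params`.
#' @export
activity_gen_params <- function(sedentary_bout_mean_min = 15,
                                sedentary_bout_sigma = 1.0,
                                active_bout_mean_min = 8,
                                active_bout_sigma = 0.75,
                                p_mvpa_given_active = 0.05,
                                sedentary_met_range = c(1.0, 1.5),
                                light_met_range = c(1.6, 2.9),
                                mvpa_met_range = c(3.0, 6.0),
                                wear_start_hour = 7,
                                wear_end_hour = 21,
                                p_midday_nonwear = 0.15,
                                midday_nonwear_mean_min = 90,
                                n_days = 10,
                                between_participant_sd = 0.4) {
  p <- as.list(environment())
  stopifnot(
    p$sedentary_bout_mean_min > 0, p$active_bout_mean_min > 0,
    p$p_mvpa_given_active >= 0, p$p_mvpa_given_active <= 1,
    p$p_midday_nonwear >= 0, p$p_midday_nonwear <= 1,
    p$n_days >= 1, p$between_participant_sd >= 0,
    p$midday_nonwear_mean_min >= 60
  )
  if ((p$wear_end_hour - p$wear_start_hour) < 10) {
    stop("wear window must span at least 10 hours", call. = FALSE)
  }
  if (p$sedentary_met_range[1] < 0.9 || p$sedentary_met_range[2] > 1.5 ||
      p$light_met_range[1] <= 1.5 || p$light_met_range[2] >= 3.0 ||
      p$mvpa_met_range[1] < 3.0) {
    stop("MET ranges inconsistent with the 1.5/3.0 intensity thresholds",
         call. = FALSE)
  }
  structure(p, class = "activity_gen_params")
}

#' Outcome generator parameters
#'
#' Encodes the proportional-hazards structure the survival analysis assumes:
#' a constant baseline hazard, true log hazard ratios for prolonged-sedentary
#' quartiles 2--4 against quartile 1, and modest sex and age effects. The
#' default baseline hazard (0.031/year) is tuned so that, with the default
#' quartile HRs of 2.72 / 2.42 / 2.85 (mean relative hazard ~2.25 across
#' quartiles), the expected 3-year cumulative incidence sits near the
#' study's design scale of 83 events among 430 participants (~19%):
#' solve 1 - exp(-h * 2.25 * 3) = 0.19 for h.
#'
#' @param true_log_hr_by_quartile length-3 numeric, log-HRs for Q2--Q4.
#' @param baseline_hazard_per_year constant baseline hazard (> 0).
#' @param followup_years number of annual checkups after baseline.
#' @param covariate_log_hrs named numeric: `sex_female` (female vs male) and
#'   `age` (per year, applied to age centred at 52).
#' @param interaction_sex_log_hr optional extra log-HR per quartile score
#'   unit for women (0 = no effect modification; used to build generators
#'   with a known sex-by-exposure interaction).
#' @param med_prob probability that an affected blood-pressure, glucose or
#'   triglyceride component at baseline carries its medication flag.
#' @return validated parameter list of class `outcome_gen_params`.
#' @export
outcome_gen_params <- function(true_log_hr_by_quartile = log(c(2.72, 2.42,
                                                               2.85)),
                               baseline_hazard_per_year = 0.031,
                               followup_years = 3,
                               covariate_log_hrs = c(sex_female = -0.2,
                                                     age = 0.02),
                               interaction_sex_log_hr = 0,
                               med_prob = 0.25) {
  stopifnot(length(true_log_hr_by_quartile) == 3,
            baseline_hazard_per_year > 0, followup_years >= 1,
            med_prob >= 0, med_prob <= 1)
  structure(as.list(environment()), class = "outcome_gen_params")
}

round1 <- function(x) round(x, 1)

# log-normal with a given arithmetic mean on the minute scale
rlnorm_mean <- function(n, mean, sdlog) {
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# One day's wear-window minutes as an alternating renewal sequence of
# sedentary and active bouts (whole minutes, >= 1 each).
fill_wear_window <- function(n_min, params, sed_mean) {
  met <- numeric(0)
  sedentary <- stats::runif(1) < 0.5
  while (length(met) < n_min) {
    if (sedentary) {
      len <- ceiling(rlnorm_mean(1, sed_mean, params$sedentary_bout_sigma))
      vals <- round1(stats::runif(len, params$sedentary_met_range[1],
                                  params$sedentary_met_range[2]))
    } else {
      len <- ceiling(rlnorm_mean(1, params$active_bout_mean_min,
                                 params$active_bout_sigma))
      rng <- if (stats::runif(1) < params$p_mvpa_given_active)
        params$mvpa_met_range else params$light_met_range
      vals <- round1(stats::runif(len, rng[1], rng[2]))
    }
    met <- c(met, vals)
    sedentary <- !sedentary
  }
  met[seq_len(n_min)]
}

#' Generate synthetic epoch traces
#'
#' Emits full 1440-minute MET traces for `n_participants` x `n_days`
#' participant-days: sub-1.0-MET values outside the wear window (the device
#' left recording on a table), alternating sedentary/active bouts inside it,
#' and optional midday non-wear gaps.
#'
#' @param params [activity_gen_params()].
#' @param n_participants number of participants (>= 1).
#' @param seed integer seed; identical `(params, n_participants, seed)` give
#'   identical traces.
#' @param start_date first measurement day.
#' @return `data.frame` in the epoch-CSV layout: `participant_id`, `date`,
#'   `minute` (0--1439), `met` (1 decimal).
#' @export
generate_epoch_traces <- function(params, n_participants, seed,
                                  start_date = as.Date("2010-04-01")) {
  if (!inherits(params, "activity_gen_params")) {
    params <- do.call(activity_gen_params, params)
  }
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  set.seed(seed)
  ws <- as.integer(params$wear_start_hour * 60)
  we <- as.integer(params$wear_end_hour * 60)
  out <- vector("list", n_participants * params$n_days)
  k <- 0L
  for (i in seq_len(n_participants)) {
    pid <- sprintf("P%04d", i)
    sed_mean <- params$sedentary_bout_mean_min *
      exp(stats::rnorm(1, 0, params$between_participant_sd))
    for (d in seq_len(params$n_days)) {
      met <- round1(stats::runif(MINUTES_PER_DAY, 0.0, 0.9))
      met[(ws + 1L):we] <- fill_wear_window(we - ws, params, sed_mean)
      if (stats::runif(1) < params$p_midday_nonwear) {
        gap <- max(60L, as.integer(round(
          rlnorm_mean(1, params$midday_nonwear_mean_min, 0.3))))
        gap <- min(gap, (we - ws) %/% 2L)
        third <- (we - ws) %/% 3L
        gs <- ws + third + as.integer(stats::runif(1) * (third - gap))
        met[(gs + 1L):(gs + gap)] <- round1(stats::runif(gap, 0.0, 0.9))
      }
      k <- k + 1L
      out[[k]] <- data.frame(
        participant_id = pid,
        date = start_date + (d - 1L),
        minute = 0:(MINUTES_PER_DAY - 1L),
        met = met,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Generate baseline covariates
#'
#' Marginals loosely patterned on the study population: 12.5% women by
#' default, ages uniform on 40--64, ~60% college-educated, ~32% current
#' smokers, household income 12/62/26% across <4M / 4--8M / >=8M JPY.
#'
#' @param n_participants number of participants (>= 1).
#' @param seed integer seed.
#' @param p_female,p_college,p_smoker marginal probabilities.
#' @param income_probs length-3 probabilities for the income categories.
#' @return `data.frame`: `participant_id`, `sex`, `age`, `education`,
#'   `smoker`, `income`.
#' @export
generate_covariates <- function(n_participants, seed, p_female = 0.125,
                                p_college = 0.6, p_smoker = 0.32,
                                income_probs = c(0.12, 0.62, 0.26)) {
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  set.seed(seed)
  data.frame(
    participant_id = sprintf("P%04d", seq_len(n_participants)),
    sex = ifelse(stats::runif(n_participants) < p_female, "female", "male"),
    age = sample(40:64, n_participants, replace = TRUE),
    education = ifelse(stats::runif(n_participants) < p_college,
                       "college+", "below"),
    smoker = ifelse(stats::runif(n_participants) < p_smoker, "yes", "no"),
    income = sample(c("<4M", "4-8M", ">=8M"), n_participants, replace = TRUE,
                    prob = income_probs),
    stringsAsFactors = FALSE
  )
}

# Vectorized biomarker panel construction: values are drawn strictly inside
# or outside each JIS threshold with a safety margin of at least one
# measurement unit, so classification round-trips exactly at stated
# precision.
panel_values <- function(affected, male) {
  n <- length(male)
  draw <- function(lo, hi) stats::runif(n, lo, hi)
  data.frame(
    waist_cm = round1(ifelse(
      affected[, 1],
      ifelse(male, draw(91, 104), draw(86, 99)),
      ifelse(male, draw(76, 88), draw(70, 83)))),
    sbp_mmHg = round(ifelse(affected[, 2], draw(132, 160), draw(105, 125))),
    dbp_mmHg = round(ifelse(affected[, 2], draw(87, 100), draw(65, 80))),
    glucose_mmol_per_L = round1(ifelse(affected[, 3], draw(5.8, 7.5),
                                       draw(4.4, 5.4))),
    hdl_mmol_per_L = round1(ifelse(
      affected[, 4],
      ifelse(male, draw(0.6, 0.85), draw(0.8, 1.15)),
      ifelse(male, draw(1.15, 1.9), draw(1.45, 2.2)))),
    tg_mmol_per_L = round1(ifelse(affected[, 5], draw(1.9, 3.5),
                                  draw(0.6, 1.45)))
  )
}

# Draw component patterns for given target counts; returns n x 5 logical.
draw_patterns <- function(counts) {
  t(vapply(counts, function(k) {
    flags <- rep(FALSE, 5)
    if (k > 0) flags[sample(5, k)] <- TRUE
    flags
  }, logical(5)))
}

#' Construct a biomarker panel with a given component count
#'
#' Inverse of the JIS-2009 classification: returns a panel whose
#' [classify_components()] count equals `target_count` exactly. Which
#' components are affected is chosen uniformly at random among subsets of
#' that size, and measurement values are drawn with a safety margin of at
#' least one measurement unit on the correct side of each threshold.
#'
#' @param target_count integer 0--5.
#' @param sex `"male"` or `"female"`.
#' @param seed optional integer seed (omit to use the current RNG stream).
#' @param med_prob probability that an affected BP/glucose/TG component is
#'   additionally marked as medicated (the component stays affected).
#' @return one-row biomarker panel `data.frame`.
#' @export
biomarkers_from_status <- function(target_count, sex, seed = NULL,
                                   med_prob = 0) {
  if (!is.numeric(target_count) || length(target_count) != 1L ||
      is.na(target_count) || target_count < 0 || target_count > 5 ||
      target_count != round(target_count)) {
    stop("`target_count` must be an integer in 0..5", call. = FALSE)
  }
  if (!sex %in% c("male", "female")) stop("unknown sex", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  affected <- draw_patterns(as.integer(target_count))
  vals <- panel_values(affected, male = sex == "male")
  med <- affected[, c(2, 3, 5), drop = FALSE] &
    matrix(stats::runif(3) < med_prob, 1)
  cbind(
    data.frame(sex = sex, stringsAsFactors = FALSE),
    vals,
    data.frame(on_antihypertensive = med[, 1], on_hypoglycemic = med[, 2],
               on_lipid_lowering = med[, 3])
  )
}

#' Generate visit-level biomarker panels with proportional-hazards onset
#'
#' Latent metabolic-syndrome onset time is exponential with hazard
#' `baseline_hazard_per_year * exp(lp)`, where the linear predictor combines
#' the participant's prolonged-sedentary quartile effect (Q1 reference) and
#' the covariate effects. Onset is observed at the first annual checkup at or
#' after it. Every baseline panel classifies to fewer than 3 components
#' (cohort MetS-free at baseline); visits from the onset checkup onward
#' classify to 3 or more. Onset is absorbing.
#'
#' @param exposures exposure rows for one variable/cutoff (needs
#'   `participant_id`, `quartile`).
#' @param covariates [generate_covariates()] output for the same
#'   participants.
#' @param params [outcome_gen_params()].
#' @param seed optional integer seed.
#' @param baseline_date first exam date for every participant.
#' @return `data.frame` of visit rows: `participant_id`, `exam_date`, `sex`,
#'   the biomarker columns, and medication flags.
#' @export
generate_outcomes <- function(exposures, covariates,
                              params = outcome_gen_params(), seed = NULL,
                              baseline_date = as.Date("2010-06-01")) {
  if (!inherits(params, "outcome_gen_params")) {
    params <- do.call(outcome_gen_params, params)
  }
  if (!is.null(seed)) set.seed(seed)
  if (!setequal(exposures$participant_id, covariates$participant_id)) {
    stop("exposures and covariates cover different participants",
         call. = FALSE)
  }
  cov <- covariates[order(covariates$participant_id), , drop = FALSE]
  q <- exposures$quartile[match(cov$participant_id,
                                exposures$participant_id)]
  n <- nrow(cov)
  female <- cov$sex == "female"
  lp <- c(0, params$true_log_hr_by_quartile)[q] +
    params$covariate_log_hrs["sex_female"] * female +
    params$covariate_log_hrs["age"] * (cov$age - 52) +
    params$interaction_sex_log_hr * q * female
  onset <- stats::rexp(n, rate = params$baseline_hazard_per_year * exp(lp))
  onset_visit <- ceiling(onset)            # first annual checkup at/after
  onset_visit[onset_visit > params$followup_years] <- Inf

  # visits run annually from baseline (year 0) to the onset checkup or the
  # last scheduled checkup; baseline component counts are 0-2 (pattern from
  # the study's baseline table), post-onset counts 3-5
  n_visits <- ifelse(is.finite(onset_visit), onset_visit,
                     params$followup_years) + 1L
  idx <- rep(seq_len(n), n_visits)
  year <- sequence(n_visits) - 1L
  is_onset <- year >= onset_visit[idx]
  counts <- integer(length(idx))
  counts[!is_onset] <- sample(0:2, sum(!is_onset), replace = TRUE,
                              prob = c(0.30, 0.42, 0.28))
  counts[is_onset] <- sample(3:5, sum(is_onset), replace = TRUE,
                             prob = c(0.8, 0.15, 0.05))
  affected <- draw_patterns(counts)
  vals <- panel_values(affected, male = !female[idx])
  med <- affected[, c(2, 3, 5), drop = FALSE] &
    matrix(stats::runif(3 * length(idx)) < params$med_prob,
           ncol = 3)
  med[year != 0L, ] <- FALSE               # flags used at baseline only
  cbind(
    data.frame(participant_id = cov$participant_id[idx],
               exam_date = baseline_date + round(365.25 * year),
               sex = cov$sex[idx], stringsAsFactors = FALSE),
    vals,
    data.frame(on_antihypertensive = med[, 1], on_hypoglycemic = med[, 2],
               on_lipid_lowering = med[, 3])
  )
}

#' Generate participant-level activity summaries directly
#'
#' For survival-scale simulations the epoch engine is unnecessary: this
#' draws each participant's mean daily prolonged(30) and non-prolonged(30)
#' sedentary time from independent sex-specific log-normal distributions
#' whose quartiles sit near the published sex-specific cut-offs (men
#' 106.7/165.5/269.2, women 65.1/122.7/195.4 min/day), wear time from a
#' normal distribution around 846 min/day, and weekly MVPA from a
#' right-skewed distribution with median near 50 min/week. Cut-off-10/20
#' variants are built by adding non-negative increments so that
#' prolonged(10) >= prolonged(20) >= prolonged(30) within each participant.
#'
#' @param covariates [generate_covariates()] output (sex drives the
#'   sex-specific distributions).
#' @param seed optional integer seed.
#' @return `data.frame` compatible with [build_exposures()] /
#'   [build_survival_records()]: `participant_id`, `mean_wear_min`,
#'   `mean_total_sed_min`, `mean_prolonged_sed_<c>`,
#'   `mean_nonprolonged_sed_<c>` for c in 10/20/30, `mvpa_min_per_week`.
#' @export
generate_activity_summaries <- function(covariates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(covariates)
  male <- covariates$sex == "male"
  p30 <- stats::rlnorm(n, ifelse(male, log(165.5), log(122.7)),
                       ifelse(male, 0.66, 0.8))
  n30 <- stats::rlnorm(n, ifelse(male, log(330), log(280)), 0.3)
  inc20 <- stats::rlnorm(n, log(40), 0.5)
  inc10 <- stats::rlnorm(n, log(50), 0.5)
  total <- p30 + n30
  p20 <- pmin(p30 + inc20, total)
  p10 <- pmin(p20 + inc10, total)
  data.frame(
    participant_id = covariates$participant_id,
    mean_wear_min = stats::rnorm(n, 846, 60),
    mean_total_sed_min = total,
    mean_prolonged_sed_30 = p30, mean_nonprolonged_sed_30 = total - p30,
    mean_prolonged_sed_20 = p20, mean_nonprolonged_sed_20 = total - p20,
    mean_prolonged_sed_10 = p10, mean_nonprolonged_sed_10 = total - p10,
    mvpa_min_per_week = stats::rlnorm(n, log(50), 0.9),
    stringsAsFactors = FALSE
  )
}
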