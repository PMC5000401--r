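# Threshold constants for minute-epoch classification. MET values come off the
# device with one decimal; EPS absorbs decimal-parsing noise without ever
# moving a value across a printed threshold.
MET_EPS <- 1e-6
NONWEAR_ONE_TOL <- 1e-3
SEDENTARY_MAX_MET <- 1.5
MVPA_MIN_MET <- 3.0
NONWEAR_MIN_SPAN <- 60L
NONWEAR_ALLOWANCE <- 2L
MVPA_MIN_SPAN <- 10L
MVPA_ALLOWANCE <- 2L
VALID_DAY_WEAR_MIN <- 600L
MIN_VALID_DAYS <- 4L
MINUTES_PER_DAY <- 1440L

#' Construct a one-day epoch series
#'
#' An epoch series holds one participant-day of minute-resolution MET
#' intensities. Minutes are indexed 0--1439; missing minutes may simply be
#' omitted (sparse recording).
#'
#' @param participant_id scalar identifier.
#' @param date the calendar day (`Date` or coercible).
#' @param minute integer vector of minute-of-day indices in `[0, 1439]`,
#'   strictly increasing and unique.
#' @param met numeric vector of MET intensities (>= 0), one per minute.
#' @return A `data.frame` of class `epoch_series` with columns
#'   `participant_id`, `date`, `minute`, `met`.
#' @export
epoch_series <- function(participant_id, date, minute, met) {
  minute <- as.integer(minute)
  met <- as.numeric(met)
  if (length(minute) != length(met)) {
    stop("`minute` and `met` must have equal length", call. = FALSE)
  }
  if (length(minute) > 0) {
    if (anyNA(minute) || any(minute < 0L) || any(minute >= MINUTES_PER_DAY)) {
      stop("minute indices must lie in [0, 1439]", call. = FALSE)
    }
    if (is.unsorted(minute, strictly = TRUE)) {
      stop("minute indices must be strictly increasing and unique",
           call. = FALSE)
    }
    if (anyNA(met) || any(met < 0)) {
      stop("MET values must be non-negative and non-missing", call. = FALSE)
    }
  }
  out <- data.frame(
    participant_id = rep(as.character(participant_id), length(minute)),
    date = rep(as.Date(date), length(minute)),
    minute = minute,
    met = met,
    stringsAsFactors = FALSE
  )
  class(out) <- c("epoch_series", "data.frame")
  out
}

# Expand a series (or a bare numeric vector already on the minute grid) to a
# length-1440 vector with NA at missing minutes.
met_vector <- function(series) {
  if (is.numeric(series) && is.null(dim(series))) {
    if (length(series) != MINUTES_PER_DAY) {
      stop("a bare MET vector must have length 1440", call. = FALSE)
    }
    return(as.numeric(series))
  }
  if (!is.data.frame(series) || !all(c("minute", "met") %in% names(series))) {
    stop("`series` must be an epoch_series or a length-1440 numeric vector",
         call. = FALSE)
  }
  v <- rep(NA_real_, MINUTES_PER_DAY)
  v[series$minute + 1L] <- series$met
  v
}

# Per-minute class for non-wear logic:
#   0 = sub-1.0 MET or missing (window material)
#   1 = exactly 1.0 MET at input precision (allowance material)
#   2 = above 1.0 MET (breaks a window)
nonwear_class <- function(met1440) {
  cls <- integer(MINUTES_PER_DAY)
  obs <- !is.na(met1440)
  cls[obs & abs(met1440 - 1.0) <= NONWEAR_ONE_TOL] <- 1L
  cls[obs & met1440 > 1.0 + NONWEAR_ONE_TOL] <- 2L
  cls
}

#' Detect non-wear windows in a one-day epoch series
#'
#' A non-wear window is a maximal run of at least 60 consecutive minutes with
#' estimated intensity below 1.0 MET (missing minutes count as such), allowing
#' interior runs of at most two consecutive minutes at exactly 1.0 MET. Any
#' minute above 1.0 MET, or a run of three or more 1.0-MET minutes, terminates
#' a window, and windows must start and end on sub-1.0 minutes.
#'
#' @param series an [epoch_series()] (or length-1440 numeric MET vector, `NA`
#'   for missing minutes).
#' @return `data.frame` with columns `start`, `end` (half-open minute
#'   interval) and `span` (minutes); zero rows when no window qualifies.
#' @export
detect_nonwear <- function(series) {
  cls <- nonwear_class(met_vector(series))
  r <- rle(cls)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  # A minute breaks candidacy if it is >1.0 MET or sits in a 1.0-run longer
  # than the allowance.
  breaker_run <- r$values == 2L |
    (r$values == 1L & r$lengths > NONWEAR_ALLOWANCE)
  breaker <- rep(breaker_run, r$lengths)
  cand <- rle(!breaker)
  cend <- cumsum(cand$lengths)
  cstart <- cend - cand$lengths + 1L
  out <- list()
  for (i in which(cand$values)) {
    s <- cstart[i]
    e <- cend[i]
    # trim terminal allowance minutes: windows start/end on sub-1.0 epochs
    while (s <= e && cls[s] == 1L) s <- s + 1L
    while (e >= s && cls[e] == 1L) e <- e - 1L
    if (e - s + 1L >= NONWEAR_MIN_SPAN) {
      out[[length(out) + 1L]] <- c(s - 1L, e)   # half-open, 0-based
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(), span = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2], span = m[, 2] - m[, 1])
}

# Logical length-1440 mask of minutes inside non-wear windows.
nonwear_mask <- function(nonwear) {
  mask <- rep(FALSE, MINUTES_PER_DAY)
  if (nrow(nonwear) == 0L) return(mask)
  if (any(nonwear$end <= nonwear$start)) {
    stop("malformed non-wear window", call. = FALSE)
  }
  idx <- order(nonwear$start)
  if (any(nonwear$start[idx][-1] < nonwear$end[idx][-nrow(nonwear)])) {
    stop("non-wear windows overlap", call. = FALSE)
  }
  for (i in seq_len(nrow(nonwear))) {
    mask[(nonwear$start[i] + 1L):nonwear$end[i]] <- TRUE
  }
  mask
}

#' Wear time for a one-day epoch series
#'
#' Counts minutes of the day that were recorded and fall outside every
#' detected non-wear window.
#'
#' @inheritParams detect_nonwear
#' @param nonwear the window table from [detect_nonwear()] on the same series.
#' @return integer minutes of wear.
#' @export
wear_minutes <- function(series, nonwear = detect_nonwear(series)) {
  met <- met_vector(series)
  sum(!is.na(met) & !nonwear_mask(nonwear))
}

#' Detect sedentary bouts
#'
#' A sedentary bout is a maximal run of consecutive worn minutes at <= 1.5
#' METs with no interruption: a single minute above 1.5 METs, a non-wear
#' window, a missing minute or the day boundary ends the bout.
#'
#' @inheritParams wear_minutes
#' @return `data.frame` with columns `start`, `end` (half-open) and `length`
#'   in minutes.
#' @export
detect_sedentary_bouts <- function(series, nonwear = detect_nonwear(series)) {
  met <- met_vector(series)
  sed <- !is.na(met) & !nonwear_mask(nonwear) &
    met <= SEDENTARY_MAX_MET + MET_EPS
  r <- rle(sed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    start = starts[keep] - 1L,
    end = ends[keep],
    length = r$lengths[keep]
  )
}

#' Accumulate sedentary bout time at a cut-off
#'
#' Splits total sedentary time into time accumulated in prolonged bouts
#' (length >= cut-off) and non-prolonged bouts (length < cut-off). The primary
#' cut-off is 30 minutes; 10 and 20 are the sensitivity-analysis values.
#'
#' @param bouts bout table from [detect_sedentary_bouts()].
#' @param cutoff bout-length cut-off in minutes (> 0).
#' @return named numeric vector `c(prolonged, nonprolonged, total)`.
#' @export
accumulate_bout_time <- function(bouts, cutoff = 30) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("`cutoff` must be a single positive number of minutes", call. = FALSE)
  }
  long <- bouts$length >= cutoff
  c(
    prolonged = sum(bouts$length[long]),
    nonprolonged = sum(bouts$length[!long]),
    total = sum(bouts$length)
  )
}

#' Detect MVPA periods
#'
#' An MVPA period is an interval of at least 10 minutes that starts and ends
#' on minutes at >= 3.0 METs and contains at most 2 cumulative minutes of
#' worn non-MVPA activity. Non-wear windows, missing minutes and the day
#' boundary end a period. Periods are found by a greedy left-to-right scan
#' that extends the current period until its 2-minute interruption budget is
#' exceeded. `credited` counts only the >= 3.0 MET minutes.
#'
#' @inheritParams wear_minutes
#' @return `data.frame` with columns `start`, `end` (half-open), `span` and
#'   `credited`.
#' @export
detect_mvpa_periods <- function(series, nonwear = detect_nonwear(series)) {
  met <- met_vector(series)
  worn <- !is.na(met) & !nonwear_mask(nonwear)
  is_mvpa <- worn & met >= MVPA_MIN_MET - MET_EPS
  out <- list()
  # worn segments (between barriers) are scanned independently
  wr <- rle(worn)
  wend <- cumsum(wr$lengths)
  wstart <- wend - wr$lengths + 1L
  for (g in which(wr$values)) {
    seg_start <- wstart[g]
    seg_end <- wend[g]
    i <- seg_start
    repeat {
      while (i <= seg_end && !is_mvpa[i]) i <- i + 1L
      if (i > seg_end) break
      used <- 0L
      last_mvpa <- i
      k <- i + 1L
      while (k <= seg_end) {
        if (is_mvpa[k]) {
          last_mvpa <- k
        } else {
          used <- used + 1L
          if (used > MVPA_ALLOWANCE) break
        }
        k <- k + 1L
      }
      span <- last_mvpa - i + 1L
      if (span >= MVPA_MIN_SPAN) {
        out[[length(out) + 1L]] <-
          c(i - 1L, last_mvpa, span, sum(is_mvpa[i:last_mvpa]))
      }
      i <- last_mvpa + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      span = integer(), credited = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2], span = m[, 3], credited = m[, 4])
}

#' Summarize one participant-day
#'
#' Runs non-wear detection, wear-time counting, sedentary-bout detection with
#' accumulation at the 10/20/30-minute cut-offs, and MVPA-period detection; a
#' day is valid when it has at least 600 minutes of wear.
#'
#' @inheritParams detect_nonwear
#' @param cutoffs bout-length cut-offs (minutes) at which to accumulate.
#' @return one-row `data.frame`: `participant_id`, `date`, `wear_min`,
#'   `total_sed_min`, `prolonged_sed_<c>` / `nonprolonged_sed_<c>` per
#'   cut-off, `mvpa_credited_min`, `is_valid`.
#' @export
summarize_day <- function(series, cutoffs = c(10, 20, 30)) {
  nw <- detect_nonwear(series)
  wear <- wear_minutes(series, nw)
  bouts <- detect_sedentary_bouts(series, nw)
  mvpa <- detect_mvpa_periods(series, nw)
  out <- data.frame(
    participant_id = if (is.data.frame(series) && nrow(series) > 0)
      series$participant_id[1] else NA_character_,
    date = if (is.data.frame(series) && nrow(series) > 0)
      series$date[1] else as.Date(NA),
    wear_min = wear,
    total_sed_min = sum(bouts$length),
    stringsAsFactors = FALSE
  )
  for (cutoff in cutoffs) {
    acc <- accumulate_bout_time(bouts, cutoff)
    out[[paste0("prolonged_sed_", cutoff)]] <- unname(acc["prolonged"])
    out[[paste0("nonprolonged_sed_", cutoff)]] <- unname(acc["nonprolonged"])
  }
  out$mvpa_credited_min <- sum(mvpa$credited)
  out$is_valid <- wear >= VALID_DAY_WEAR_MIN
  out
}

#' Summarize a participant over days
#'
#' Averages daily metrics over valid days only (wear >= 600 min). A
#' participant is included in analyses only with at least four valid days;
#' otherwise the summary row is flagged `included = FALSE` and all averages
#' are `NA`. Weekly MVPA is 7 x the mean daily credited MVPA minutes.
#'
#' @param days `data.frame` of daily rows from [summarize_day()] for one
#'   participant.
#' @return one-row `data.frame` with mean metrics, `n_valid_days`,
#'   `mvpa_min_per_week` and `included`.
#' @export
summarize_participant <- function(days) {
  if (nrow(days) < 1L) stop("at least one day is required", call. = FALSE)
  valid <- days[days$is_valid, , drop = FALSE]
  n_valid <- nrow(valid)
  metric_cols <- setdiff(
    names(days), c("participant_id", "date", "is_valid"))
  out <- data.frame(
    participant_id = days$participant_id[1],
    n_valid_days = n_valid,
    included = n_valid >= MIN_VALID_DAYS,
    stringsAsFactors = FALSE
  )
  for (col in metric_cols) {
    out[[paste0("mean_", col)]] <-
      if (n_valid > 0) mean(valid[[col]]) else NA_real_
  }
  out$mvpa_min_per_week <-
    if (n_valid > 0) 7 * mean(valid$mvpa_credited_min) else NA_real_
  out
}
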