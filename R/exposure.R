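#' Wear-time adjustment by the residual method
#'
#' Regresses participant-level sedentary time (min/day) on wear time
#' (min/day) by ordinary least squares, pooled over sexes, and returns each
#' participant's residual re-centred at the prediction for the cohort-mean
#' wear time. Adjusted values therefore stay on the min/day scale, have the
#' same mean as the raw values, and have exactly zero least-squares slope on
#' wear time. When wear time has zero variance the slope is defined as 0 and
#' the raw values are returned unchanged.
#'
#' @param values numeric vector of per-participant mean minutes/day.
#' @param wear numeric vector of per-participant mean wear minutes/day.
#' @return numeric vector of adjusted minutes/day.
#' @export
residual_adjust <- function(values, wear) {
  if (length(values) != length(wear)) {
    stop("`values` and `wear` must have equal length", call. = FALSE)
  }
  if (length(values) < 3L) {
    stop("residual adjustment needs at least 3 participants", call. = FALSE)
  }
  if (!all(is.finite(values)) || !all(is.finite(wear))) {
    stop("non-finite values in residual adjustment input", call. = FALSE)
  }
  w_centered <- wear - mean(wear)
  ssw <- sum(w_centered^2)
  slope <- if (ssw > 0) sum(w_centered * values) / ssw else 0
  # residual + prediction at mean wear == values - slope * (wear - mean(wear))
  values - slope * w_centered
}

#' Sex-specific quartile assignment
#'
#' Within each sex stratum, computes the 25th/50th/75th percentile cut-points
#' by linear interpolation between order statistics and assigns quartile
#' labels 1--4 (ascending). A value exactly equal to a cut-point goes to the
#' lower quartile.
#'
#' @param adjusted numeric vector (typically wear-time-adjusted min/day).
#' @param sex character/factor vector of the same length.
#' @return list with `quartile` (integer vector 1--4) and `cutpoints` (named
#'   list per sex of the three cut-points).
#' @export
sex_specific_quartiles <- function(adjusted, sex) {
  if (length(adjusted) != length(sex)) {
    stop("`adjusted` and `sex` must have equal length", call. = FALSE)
  }
  sex <- as.character(sex)
  quartile <- integer(length(adjusted))
  cutpoints <- list()
  for (s in unique(sex)) {
    idx <- which(sex == s)
    if (length(idx) < 4L) {
      stop(sprintf("sex stratum '%s' has fewer than 4 members", s),
           call. = FALSE)
    }
    cp <- unname(stats::quantile(adjusted[idx], probs = c(.25, .5, .75),
                                 type = 7))
    # equal-to-cut-point goes to the lower quartile
    quartile[idx] <- 1L + (adjusted[idx] > cp[1]) + (adjusted[idx] > cp[2]) +
      (adjusted[idx] > cp[3])
    cutpoints[[s]] <- cp
  }
  list(quartile = quartile, cutpoints = cutpoints)
}

#' Build analysis exposures from participant activity summaries
#'
#' For each sedentary variable (total, prolonged, non-prolonged) at each bout
#' cut-off, adjusts the participant-level mean for wear time by the residual
#' method (pooled over sexes) and assigns sex-specific quartiles.
#'
#' @param participants `data.frame` of included participant summaries (one
#'   row each) carrying `participant_id`, `mean_wear_min`,
#'   `mean_total_sed_min`, `mean_prolonged_sed_<c>`,
#'   `mean_nonprolonged_sed_<c>` columns.
#' @param sex character vector aligned with `participants` rows.
#' @param cutoffs bout cut-offs to build exposures for.
#' @return list with `exposures` (long `data.frame`: `participant_id`,
#'   `variable`, `cutoff`, `raw`, `wear`, `adjusted`, `quartile`, `sex`) and
#'   `cutpoints` (nested list by variable/cutoff/sex).
#' @export
build_exposures <- function(participants, sex, cutoffs = c(10, 20, 30)) {
  if (nrow(participants) != length(sex)) {
    stop("`sex` must align with `participants` rows", call. = FALSE)
  }
  wear <- participants$mean_wear_min
  rows <- list()
  cutpoints <- list()
  for (cutoff in cutoffs) {
    vars <- list(
      total = participants$mean_total_sed_min,
      prolonged = participants[[paste0("mean_prolonged_sed_", cutoff)]],
      nonprolonged = participants[[paste0("mean_nonprolonged_sed_", cutoff)]]
    )
    for (vn in names(vars)) {
      adj <- residual_adjust(vars[[vn]], wear)
      q <- sex_specific_quartiles(adj, sex)
      key <- paste0(vn, "_", cutoff)
      cutpoints[[key]] <- q$cutpoints
      rows[[key]] <- data.frame(
        participant_id = participants$participant_id,
        variable = vn,
        cutoff = cutoff,
        raw = vars[[vn]],
        wear = wear,
        adjusted = adj,
        quartile = q$quartile,
        sex = as.character(sex),
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    exposures = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    cutpoints = cutpoints
  )
}
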