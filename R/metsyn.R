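# Joint Interim Statement 2009 thresholds
WAIST_CUT_M <- 90
WAIST_CUT_F <- 85
SBP_CUT <- 130
DBP_CUT <- 85
GLUCOSE_CUT <- 5.6
HDL_CUT_M <- 1.0
HDL_CUT_F <- 1.3
TG_CUT <- 1.7
METS_MIN_COMPONENTS <- 3L

#' Classify the five metabolic-syndrome components
#'
#' Applies the Joint Interim Statement 2009 criteria to one or more visit
#' panels: central obesity (waist >= 90 cm men / >= 85 cm women), elevated
#' blood pressure (SBP >= 130 or DBP >= 85 mmHg, or antihypertensive
#' medication), elevated fasting glucose (>= 5.6 mmol/L or hypoglycemic
#' medication), low HDL-cholesterol (< 1.0 mmol/L men / < 1.3 mmol/L women),
#' and hypertriglyceridemia (>= 1.7 mmol/L or lipid-lowering medication).
#'
#' A missing measurement is tolerated only when a medication flag already
#' forces that component; otherwise it is a missing-data error (such
#' participants are excluded upstream).
#'
#' @param panels `data.frame` with columns `sex` (`"male"`/`"female"`),
#'   `waist_cm`, `sbp_mmHg`, `dbp_mmHg`, `glucose_mmol_per_L`,
#'   `hdl_mmol_per_L`, `tg_mmol_per_L`, `on_antihypertensive`,
#'   `on_hypoglycemic`, `on_lipid_lowering`.
#' @return `data.frame` with logical columns `central_obesity`,
#'   `elevated_bp`, `elevated_glucose`, `low_hdl`, `high_tg` and integer
#'   `count`.
#' @export
classify_components <- function(panels) {
  req <- c("sex", "waist_cm", "sbp_mmHg", "dbp_mmHg", "glucose_mmol_per_L",
           "hdl_mmol_per_L", "tg_mmol_per_L", "on_antihypertensive",
           "on_hypoglycemic", "on_lipid_lowering")
  missing_cols <- setdiff(req, names(panels))
  if (length(missing_cols) > 0) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sex <- as.character(panels$sex)
  if (!all(sex %in% c("male", "female"))) {
    stop("`sex` must be 'male' or 'female'", call. = FALSE)
  }
  male <- sex == "male"
  anti_hyp <- as.logical(panels$on_antihypertensive)
  hypo <- as.logical(panels$on_hypoglycemic)
  lipid <- as.logical(panels$on_lipid_lowering)

  need <- function(x, covered, what) {
    bad <- is.na(x) & !covered
    if (any(bad)) {
      stop(sprintf("missing %s without a covering medication flag (row %d)",
                   what, which(bad)[1]), call. = FALSE)
    }
  }
  need(panels$waist_cm, FALSE, "waist circumference")
  need(panels$sbp_mmHg, anti_hyp, "systolic blood pressure")
  need(panels$dbp_mmHg, anti_hyp, "diastolic blood pressure")
  need(panels$glucose_mmol_per_L, hypo, "fasting glucose")
  need(panels$hdl_mmol_per_L, FALSE, "HDL-cholesterol")
  need(panels$tg_mmol_per_L, lipid, "triglycerides")

  or_na <- function(a, b) ifelse(is.na(a), b, a | b)
  central_obesity <- panels$waist_cm >= ifelse(male, WAIST_CUT_M, WAIST_CUT_F)
  elevated_bp <- or_na(panels$sbp_mmHg >= SBP_CUT | panels$dbp_mmHg >= DBP_CUT,
                       anti_hyp)
  elevated_glucose <- or_na(panels$glucose_mmol_per_L >= GLUCOSE_CUT, hypo)
  low_hdl <- panels$hdl_mmol_per_L < ifelse(male, HDL_CUT_M, HDL_CUT_F)
  high_tg <- or_na(panels$tg_mmol_per_L >= TG_CUT, lipid)

  out <- data.frame(
    central_obesity = central_obesity,
    elevated_bp = elevated_bp,
    elevated_glucose = elevated_glucose,
    low_hdl = low_hdl,
    high_tg = high_tg
  )
  out$count <- as.integer(rowSums(out))
  out
}

#' Metabolic syndrome from component status
#'
#' Positive when at least 3 of the 5 components are present.
#'
#' @param status output of [classify_components()] (or anything with a
#'   `count` column / integer vector of counts).
#' @return logical vector.
#' @export
classify_mets <- function(status) {
  count <- if (is.data.frame(status)) status$count else as.integer(status)
  count >= METS_MIN_COMPONENTS
}

#' Assemble person-time survival records
#'
#' Person-time runs from the baseline examination to the first
#' metabolic-syndrome-positive examination (event) or the last attended
#' examination (censoring), whichever comes first. Participants positive at
#' baseline are excluded, as are participants with no post-baseline visit;
#' both exclusions are counted in the `exclusions` attribute. A participant
#' who skips a checkup but is positive at the next attended one contributes
#' an event at that observed positive exam.
#'
#' @param visits `data.frame` of biomarker panels, one row per
#'   participant-visit, with `participant_id`, `exam_date` and the
#'   [classify_components()] columns; rows need not be pre-sorted but exam
#'   dates must be unique per participant.
#' @param covariates `data.frame` with one row per participant:
#'   `participant_id`, `sex`, `age`, `education`, `smoker`, `income`.
#' @param exposures optional long exposure table from [build_exposures()];
#'   quartiles are spread into `quartile_<variable>_<cutoff>` columns.
#' @param mvpa optional `data.frame` `participant_id`, `mvpa_min_per_week`.
#' @return `data.frame` of survival records (`time_days`, `time_years`,
#'   `event`, covariates, `baseline_waist_cm`, `baseline_components`,
#'   medication flags at baseline, quartile columns), with attribute
#'   `exclusions` (named counts).
#' @export
build_survival_records <- function(visits, covariates, exposures = NULL,
                                   mvpa = NULL) {
  comp <- classify_components(visits)
  v <- visits
  v$mets <- classify_mets(comp)
  v$components <- comp$count
  v <- v[order(v$participant_id, v$exam_date), , drop = FALSE]
  if (anyDuplicated(v[, c("participant_id", "exam_date")])) {
    stop("duplicate exam dates within a participant", call. = FALSE)
  }
  first <- !duplicated(v$participant_id)
  last <- !duplicated(v$participant_id, fromLast = TRUE)
  pid_levels <- v$participant_id[first]
  grp <- match(v$participant_id, pid_levels)

  baseline_mets <- v$mets[first]
  n_visits <- tabulate(grp, nbins = length(pid_levels))
  keep <- !baseline_mets & n_visits >= 2L
  excl <- c(baseline_mets = sum(baseline_mets),
            no_followup = sum(!baseline_mets & n_visits < 2L))
  if (!any(keep)) {
    stop("no participants remain after baseline screening", call. = FALSE)
  }
  # first post-baseline MetS-positive exam per participant, if any
  pos <- which(!first & v$mets)
  pos <- pos[!duplicated(grp[pos])]
  event_date <- rep(as.Date(NA), length(pid_levels))
  event_date[grp[pos]] <- v$exam_date[pos]
  last_date <- v$exam_date[last]
  baseline_date <- v$exam_date[first]
  has_event <- !is.na(event_date)
  end_date <- ifelse(has_event, event_date, last_date)
  time_days <- as.numeric(end_date - as.numeric(baseline_date))
  rec <- data.frame(
    participant_id = pid_levels,
    time_days = time_days,
    time_years = time_days / 365.25,
    event = as.integer(has_event),
    baseline_components = v$components[first],
    baseline_waist_cm = v$waist_cm[first],
    on_medication = as.logical(v$on_antihypertensive[first] |
                                 v$on_hypoglycemic[first] |
                                 v$on_lipid_lowering[first]),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(rec) <- NULL
  if (any(rec$time_days <= 0)) {
    stop("non-positive follow-up time: exam dates unordered?", call. = FALSE)
  }
  rec <- merge(rec, covariates, by = "participant_id", sort = TRUE)
  if (!is.null(mvpa)) {
    rec <- merge(rec, mvpa[, c("participant_id", "mvpa_min_per_week")],
                 by = "participant_id", sort = TRUE)
  }
  if (!is.null(exposures)) {
    for (key in unique(paste0(exposures$variable, "_", exposures$cutoff))) {
      sub <- exposures[paste0(exposures$variable, "_",
                              exposures$cutoff) == key, ]
      qcol <- sub[, c("participant_id", "quartile")]
      names(qcol)[2] <- paste0("quartile_", key)
      rec <- merge(rec, qcol, by = "participant_id", sort = TRUE)
    }
  }
  attr(rec, "exclusions") <- excl
  rec
}

#' Incidence rate per 1000 person-years
#'
#' @param records survival records from [build_survival_records()].
#' @param by optional grouping vector aligned with `records` rows.
#' @return a single rate, or a `data.frame` of per-group rates when `by` is
#'   supplied.
#' @export
incidence_rate <- function(records, by = NULL) {
  rate1 <- function(ev, yr) {
    if (sum(yr) <= 0) stop("zero total person-time", call. = FALSE)
    1000 * sum(ev) / sum(yr)
  }
  if (is.null(by)) {
    return(rate1(records$event, records$time_years))
  }
  groups <- split(seq_len(nrow(records)), by)
  data.frame(
    group = names(groups),
    events = vapply(groups, function(i) sum(records$event[i]), numeric(1)),
    person_years = vapply(groups, function(i) sum(records$time_years[i]),
                          numeric(1)),
    rate_per_1000py = vapply(
      groups, function(i) rate1(records$event[i], records$time_years[i]),
      numeric(1)),
    row.names = NULL
  )
}
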