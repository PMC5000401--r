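EPOCH_COLS <- c("participant_id", "date", "minute", "met")
PANEL_COLS <- c("participant_id", "exam_date", "sex", "waist_cm", "sbp_mmHg",
                "dbp_mmHg", "glucose_mmol_per_L", "hdl_mmol_per_L",
                "tg_mmol_per_L", "on_antihypertensive", "on_hypoglycemic",
                "on_lipid_lowering")
COVARIATE_COLS <- c("age", "education", "smoker", "income")

#' Read an epoch CSV
#'
#' Epoch files carry one row per recorded minute: `participant_id`, `date`
#' (ISO-8601), `minute` (0--1439) and `met` (1-decimal float). Rows may be
#' sparse (missing minutes omitted). Schema violations raise errors naming
#' the offending line; unknown columns only warn.
#'
#' @param path CSV file path.
#' @return validated `data.frame` in epoch layout, sorted by participant,
#'   date, minute.
#' @export
read_epoch_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(EPOCH_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop("epoch file missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), EPOCH_COLS)
  if (length(extra) > 0) {
    warning("ignoring unknown epoch columns: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  raw <- raw[EPOCH_COLS]
  line <- seq_len(nrow(raw)) + 1L          # header is line 1
  bad <- which(!is.finite(raw$minute) | raw$minute < 0 |
                 raw$minute > 1439 | raw$minute != round(raw$minute))
  if (length(bad) > 0) {
    stop(sprintf("invalid minute index at line %d", line[bad[1]]),
         call. = FALSE)
  }
  bad <- which(!is.finite(raw$met) | raw$met < 0)
  if (length(bad) > 0) {
    stop(sprintf("invalid MET value at line %d", line[bad[1]]),
         call. = FALSE)
  }
  date <- as.Date(raw$date)
  if (anyNA(date)) {
    stop(sprintf("unparseable date at line %d",
                 line[which(is.na(date))[1]]), call. = FALSE)
  }
  raw$date <- date
  dup <- which(duplicated(raw[, c("participant_id", "date", "minute")]))
  if (length(dup) > 0) {
    stop(sprintf("duplicated (participant, date, minute) at line %d",
                 line[dup[1]]), call. = FALSE)
  }
  raw$minute <- as.integer(raw$minute)
  raw[order(raw$participant_id, raw$date, raw$minute), , drop = FALSE]
}

#' Write an epoch CSV
#' @param epochs epoch-layout `data.frame`.
#' @param path output path.
#' @export
write_epoch_csv <- function(epochs, path) {
  epochs <- epochs[order(epochs$participant_id, epochs$date, epochs$minute),
                   , drop = FALSE]
  utils::write.csv(epochs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' One row per participant-visit carrying the biomarker panel columns;
#' baseline covariates (`age`, `education`, `smoker`, `income`) are read off
#' each participant's earliest visit row.
#'
#' @param path CSV file path.
#' @return list with `visits` (panel rows) and `covariates` (one row per
#'   participant).
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c(PANEL_COLS, COVARIATE_COLS)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), needed)
  if (length(extra) > 0) {
    warning("ignoring unknown cohort columns: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  raw$exam_date <- as.Date(raw$exam_date)
  if (anyNA(raw$exam_date)) stop("unparseable exam_date", call. = FALSE)
  for (flag in c("on_antihypertensive", "on_hypoglycemic",
                 "on_lipid_lowering")) {
    raw[[flag]] <- as.logical(raw[[flag]])
  }
  raw <- raw[order(raw$participant_id, raw$exam_date), , drop = FALSE]
  first <- !duplicated(raw$participant_id)
  list(
    visits = raw[PANEL_COLS],
    covariates = cbind(
      raw[first, c("participant_id", "sex"), drop = FALSE],
      raw[first, COVARIATE_COLS, drop = FALSE]
    )
  )
}

#' Write a cohort CSV
#' @param visits panel rows (with covariate columns merged in).
#' @param path output path.
#' @export
write_cohort_csv <- function(visits, path) {
  visits <- visits[order(visits$participant_id, visits$exam_date), ,
                   drop = FALSE]
  utils::write.csv(visits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write pipeline result tables
#'
#' Writes each element of `results` as a TSV (stable-sorted by the writers
#' upstream), lists as JSON.
#'
#' @param results named list of `data.frame`s / lists.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_tables <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(x, p, sep = "\t", row.names = FALSE, quote = FALSE)
    } else {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}
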