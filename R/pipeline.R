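#' Default pipeline configuration
#'
#' Returns the full configuration list with every default filled in; values
#' supplied in `config` (possibly nested) override defaults. The `simulate`
#' block, when present, replaces file inputs with the synthetic generator.
#'
#' @param config partial configuration list or path to a YAML file.
#' @return complete configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    epochs = NULL,                         # epoch CSV path (process mode)
    cohort = NULL,                         # cohort CSV path (process mode)
    out = "sedbouts-output",
    seed = 1L,
    cutoffs = c(10, 20, 30),
    primary_cutoff = 30,
    model_levels = 1:4,
    sensitivity = list(cutoffs = TRUE, stratified = TRUE,
                       exclude_medicated = TRUE),
    simulate = NULL
  )
  sim_defaults <- list(n_participants = 430, activity = list(),
                       outcome = list())
  out <- utils::modifyList(defaults, config)
  if (!is.null(out$simulate)) {
    out$simulate <- utils::modifyList(sim_defaults, out$simulate)
    if (is.null(out$seed)) {
      stop("a seed is required when simulating", call. = FALSE)
    }
  }
  out
}

#' Process epoch data into daily summaries
#'
#' Splits an epoch table into participant-days and runs [summarize_day()]
#' on each.
#'
#' @param epochs epoch-layout `data.frame` (see [read_epoch_csv()]).
#' @param cutoffs bout cut-offs for accumulation.
#' @return `data.frame` of daily summary rows, sorted by participant, date.
#' @export
process_epochs <- function(epochs, cutoffs = c(10, 20, 30)) {
  key <- paste(epochs$participant_id, epochs$date)
  idx <- split(seq_len(nrow(epochs)), key)
  rows <- lapply(idx, function(i) {
    summarize_day(
      structure(epochs[i, , drop = FALSE],
                class = c("epoch_series", "data.frame")),
      cutoffs = cutoffs)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$participant_id, out$date), , drop = FALSE]
}

#' Summarize all participants from daily summaries
#'
#' @param daily daily summary rows from [process_epochs()].
#' @return `data.frame`, one row per participant (including excluded ones,
#'   flagged `included = FALSE`).
#' @export
summarize_participants <- function(daily) {
  idx <- split(seq_len(nrow(daily)), daily$participant_id)
  rows <- lapply(idx, function(i) {
    summarize_participant(daily[i, , drop = FALSE])
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$participant_id), , drop = FALSE]
}

#' Run the full pipeline
#'
#' Orchestrates simulate (or read) -> daily processing -> participant
#' summaries -> exposure building -> metabolic-syndrome classification ->
#' survival records -> Cox model ladders and sensitivity analyses, writing
#' result tables and a run manifest to `config$out`.
#'
#' @param config configuration list or YAML path (see [pipeline_config()]).
#' @param write write outputs to disk (set `FALSE` to just return results).
#' @return invisibly, a named list with all intermediate and final tables
#'   plus the manifest.
#' @export
run_pipeline <- function(config = list(), write = TRUE) {
  cfg <- pipeline_config(config)
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    act <- do.call(activity_gen_params, sim$activity)
    epochs <- generate_epoch_traces(act, sim$n_participants, seed = cfg$seed)
    covariates <- generate_covariates(sim$n_participants,
                                      seed = cfg$seed + 1L)
  } else {
    if (is.null(cfg$epochs) || is.null(cfg$cohort)) {
      stop("either a simulate block or epoch+cohort paths are required",
           call. = FALSE)
    }
    epochs <- read_epoch_csv(cfg$epochs)
    cohort <- read_cohort_csv(cfg$cohort)
    covariates <- cohort$covariates
  }

  daily <- process_epochs(epochs, cutoffs = cfg$cutoffs)
  participants <- summarize_participants(daily)
  n_input <- nrow(participants)
  included <- participants[participants$included, , drop = FALSE]
  n_excluded_wear <- n_input - nrow(included)
  covariates <- covariates[covariates$participant_id %in%
                             included$participant_id, , drop = FALSE]
  covariates <- covariates[order(covariates$participant_id), , drop = FALSE]
  included <- included[order(included$participant_id), , drop = FALSE]

  exp_built <- build_exposures(included, covariates$sex,
                               cutoffs = cfg$cutoffs)
  exposures <- exp_built$exposures

  primary <- exposures[exposures$variable == "prolonged" &
                         exposures$cutoff == cfg$primary_cutoff, ]
  if (!is.null(cfg$simulate)) {
    out_params <- do.call(outcome_gen_params, cfg$simulate$outcome)
    visits <- generate_outcomes(primary, covariates, out_params,
                                seed = cfg$seed + 2L)
  } else {
    visits <- cohort$visits
  }

  mvpa <- data.frame(participant_id = included$participant_id,
                     mvpa_min_per_week = included$mvpa_min_per_week,
                     stringsAsFactors = FALSE)
  records <- build_survival_records(visits, covariates, exposures, mvpa)
  excl <- attr(records, "exclusions")

  ladders <- list()
  for (v in c("total", "prolonged", "nonprolonged")) {
    ladders[[v]] <- fit_model_ladder(records, v, cfg$primary_cutoff,
                                     levels = cfg$model_levels)
  }
  results <- list(
    daily_summaries = daily,
    participant_summaries = participants,
    exposures = exposures,
    cutpoints = exp_built$cutpoints,
    survival_records = records,
    main_results = do.call(rbind, c(unname(ladders),
                                    list(make.row.names = FALSE)))
  )
  qcol <- paste0("quartile_prolonged_", cfg$primary_cutoff)
  results$baseline_trends <- baseline_trend_tests(
    records[, c("age", "sex", "education", "smoker", "income",
                "mvpa_min_per_week", "baseline_waist_cm",
                "baseline_components")],
    records[[qcol]])
  if (isTRUE(cfg$sensitivity$cutoffs)) {
    results$sensitivity_cutoffs <- sensitivity_cutoffs(
      records, cutoffs = cfg$cutoffs, levels = max(cfg$model_levels))
  }
  if (isTRUE(cfg$sensitivity$stratified)) {
    strat <- stratified_by_components(records, "prolonged",
                                      cfg$primary_cutoff,
                                      levels = min(3, max(cfg$model_levels)))
    results$stratified_low_risk <- strat$low_risk
    results$stratified_high_risk <- strat$high_risk
  }
  if (isTRUE(cfg$sensitivity$exclude_medicated)) {
    results$sensitivity_exclude_medicated <-
      sensitivity_exclude_medicated(records, "prolonged",
                                    cfg$primary_cutoff,
                                    levels = min(3, max(cfg$model_levels)))
  }

  results$manifest <- list(
    package_version = as.character(utils::packageVersion("sedbouts")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out")],
    n_participants_input = n_input,
    n_excluded_wear_validity = n_excluded_wear,
    n_excluded_baseline_mets = unname(excl["baseline_mets"]),
    n_excluded_no_followup = unname(excl["no_followup"]),
    n_analyzed = nrow(records),
    n_events = sum(records$event),
    incidence_rate_per_1000py = incidence_rate(records)
  )
  if (write) write_tables(results, cfg$out)
  invisible(results)
}
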