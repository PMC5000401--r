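#' Fit the nested Cox model ladder for one exposure
#'
#' Reproduces the layout of the main results table: for one sedentary
#' variable at one bout cut-off, per-quartile case counts and incidence rates
#' plus hazard ratios (95% CI, Wald p) from the four nested models. Quartile
#' 1 is always the reference (HR 1).
#'
#' @param records survival records with quartile and covariate columns.
#' @param variable `"total"`, `"prolonged"` or `"nonprolonged"`.
#' @param cutoff bout cut-off in minutes.
#' @param levels which model levels to fit (subset of 1:4).
#' @return `data.frame` with one row per quartile x model: `variable`,
#'   `cutoff`, `model`, `quartile`, `n`, `cases`, `rate_per_1000py`, `hr`,
#'   `ci_lower`, `ci_upper`, `p`. Fits are attached as attribute `fits`.
#' @export
fit_model_ladder <- function(records, variable = "prolonged", cutoff = 30,
                             levels = 1:4) {
  qcol <- paste0("quartile_", variable, "_", cutoff)
  if (!qcol %in% names(records)) {
    stop("records lack exposure column ", qcol, call. = FALSE)
  }
  q <- records[[qcol]]
  rates <- incidence_rate(records, by = q)
  rows <- list()
  fits <- list()
  for (lv in levels) {
    fit <- fit_cox(records, model_spec(variable, cutoff, lv))
    fits[[paste0("model", lv)]] <- fit
    hr <- c(1, NA, NA, NA)
    lo <- c(NA, NA, NA, NA)
    hi <- c(NA, NA, NA, NA)
    p <- c(NA, NA, NA, NA)
    for (k in 2:4) {
      i <- match(paste0("Q", k), fit$terms)
      hr[k] <- fit$hr[i]; lo[k] <- fit$ci_lower[i]
      hi[k] <- fit$ci_upper[i]; p[k] <- fit$p[i]
    }
    rows[[lv]] <- data.frame(
      variable = variable, cutoff = cutoff, model = lv, quartile = 1:4,
      n = as.integer(table(factor(q, levels = 1:4))),
      cases = rates$events[match(1:4, rates$group)],
      rate_per_1000py = rates$rate_per_1000py[match(1:4, rates$group)],
      hr = hr, ci_lower = lo, ci_upper = hi, p = p,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "fits") <- fits
  out
}

#' Single-df interaction test
#'
#' Adds a product of the quartile ordinal score (1--4) with an effect
#' modifier to the specified model and returns the Wald p-value of the
#' product term. MVPA is dichotomized at 150 min/week.
#'
#' @param records survival records.
#' @param spec a [model_spec()].
#' @param modifier `"age"`, `"sex"` or `"mvpa_binary"`.
#' @return list with `p`, `coef`, `se` for the product term.
#' @export
interaction_test <- function(records, spec = model_spec(),
                             modifier = c("age", "sex", "mvpa_binary")) {
  modifier <- match.arg(modifier)
  mf <- prepare_model_frame(records)
  modnum <- switch(
    modifier,
    age = mf$age,
    sex = mf$sex_female,
    mvpa_binary = as.numeric(mf$mvpa_min_per_week >= 150)
  )
  if (stats::var(modnum) == 0) {
    stop("effect modifier '", modifier, "' is constant", call. = FALSE)
  }
  qcol <- quartile_column(spec)
  records$q_score <- as.numeric(records[[qcol]])
  records$mod_num <- modnum
  records$q_by_mod <- records$q_score * modnum
  covs <- ladder_covariates(spec$level)
  # the modifier's main effect is already in every ladder level for age and
  # sex; mvpa_binary needs its own main-effect term
  extra <- if (modifier == "mvpa_binary") c("mod_num") else character()
  spec2 <- model_spec(spec$variable, spec$cutoff, spec$level,
                      covariates = c(covs, extra, "q_by_mod"))
  fit <- fit_cox(records, spec2)
  i <- match("q_by_mod", fit$terms)
  list(p = fit$p[i], coef = fit$coef[i], se = fit$se[i], fit = fit)
}

#' Ladders stratified by baseline component count
#'
#' Fits independent model ladders in the lower-risk stratum (0--1 affected
#' components at baseline) and the higher-risk stratum (2 components).
#'
#' @inheritParams fit_model_ladder
#' @return list with `low_risk` and `high_risk` ladder tables (each with an
#'   `n` attribute) and `n_by_stratum`.
#' @export
stratified_by_components <- function(records, variable = "prolonged",
                                     cutoff = 30, levels = 3) {
  strata <- list(
    low_risk = records[records$baseline_components <= 1, , drop = FALSE],
    high_risk = records[records$baseline_components == 2, , drop = FALSE]
  )
  out <- list()
  for (nm in names(strata)) {
    s <- strata[[nm]]
    if (nrow(s) == 0L) stop("empty stratum: ", nm, call. = FALSE)
    if (sum(s$event) < 2L) {
      stop("stratum ", nm, " has fewer than 2 events", call. = FALSE)
    }
    out[[nm]] <- fit_model_ladder(s, variable, cutoff, levels)
  }
  out$n_by_stratum <- vapply(strata, nrow, integer(1))
  out
}

#' Sensitivity analysis over bout cut-offs
#'
#' Refits the model ladder for the prolonged and non-prolonged variables at
#' each bout cut-off (10, 20, 30 minutes by default).
#'
#' @inheritParams fit_model_ladder
#' @param cutoffs cut-offs to refit at.
#' @param variables exposure variables to include.
#' @return combined ladder `data.frame` over cut-offs and variables.
#' @export
sensitivity_cutoffs <- function(records, cutoffs = c(10, 20, 30),
                                variables = c("prolonged", "nonprolonged"),
                                levels = 3) {
  rows <- list()
  for (cutoff in cutoffs) {
    for (v in variables) {
      rows[[paste(v, cutoff)]] <- fit_model_ladder(records, v, cutoff, levels)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Sensitivity analysis excluding baseline medication users
#'
#' Drops participants on any baseline medication (antihypertensive,
#' hypoglycemic or lipid-lowering) and refits the MVPA-adjusted model
#' (level 3), probing the impact of treatment-induced reversibility.
#'
#' @inheritParams fit_model_ladder
#' @return ladder `data.frame` on the subset, with attributes `n_excluded`
#'   and `low_events` (TRUE when the subset has fewer than 10 events).
#' @export
sensitivity_exclude_medicated <- function(records, variable = "prolonged",
                                          cutoff = 30, levels = 3) {
  keep <- !records$on_medication
  if (!any(keep)) stop("all participants medicated: empty subset",
                       call. = FALSE)
  sub <- records[keep, , drop = FALSE]
  out <- fit_model_ladder(sub, variable, cutoff, levels)
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "low_events") <- sum(sub$event) < 10
  out
}

#' Trend tests across exposure quartiles
#'
#' For each baseline characteristic, tests for a monotone trend over
#' quartiles: binary characteristics use a Cochran--Armitage-style score
#' test with quartile scores 1--4; multi-level categorical characteristics
#' use the linear-by-linear association test with integer category scores;
#' continuous characteristics use the least-squares slope test of value on
#' quartile score. A constant characteristic yields `NA`.
#'
#' @param data `data.frame` of baseline characteristics.
#' @param quartile integer quartile labels (1--4) aligned with `data` rows.
#' @param vars characteristic columns to test (default: all columns).
#' @return `data.frame` with `characteristic`, `type` and `p_trend`.
#' @export
baseline_trend_tests <- function(data, quartile, vars = names(data)) {
  score <- as.numeric(quartile)
  res <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(x)) > 2L) {
      if (stats::var(x) == 0) {
        return(data.frame(characteristic = v, type = "continuous",
                          p_trend = NA_real_))
      }
      sm <- summary(stats::lm(x ~ score))$coefficients
      return(data.frame(characteristic = v, type = "continuous",
                        p_trend = sm["score", "Pr(>|t|)"]))
    }
    f <- factor(x)
    if (nlevels(f) < 2L) {
      return(data.frame(characteristic = v, type = "categorical",
                        p_trend = NA_real_))
    }
    if (nlevels(f) == 2L) {
      ev <- tapply(f == levels(f)[2], score, sum)
      n <- tapply(score, score, length)
      ev <- ev[order(as.numeric(names(ev)))]
      n <- n[order(as.numeric(names(n)))]
      if (all(abs(ev / n - sum(ev) / sum(n)) < 1e-12)) {
        # identical proportions: trend statistic is exactly zero
        return(data.frame(characteristic = v, type = "binary", p_trend = 1))
      }
      pt <- stats::prop.trend.test(ev, n, score = sort(unique(score)))
      return(data.frame(characteristic = v, type = "binary",
                        p_trend = pt$p.value))
    }
    # linear-by-linear association, M^2 = (n-1) r^2
    r <- stats::cor(as.numeric(f), score)
    m2 <- (length(score) - 1) * r^2
    data.frame(characteristic = v, type = "categorical",
               p_trend = stats::pchisq(m2, df = 1, lower.tail = FALSE))
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Log-minus-log survival curves by quartile
#'
#' Emits the complementary log-log transformed Kaplan--Meier curves used to
#' eyeball proportional hazards; purely graphical, nothing is asserted.
#'
#' @inheritParams fit_model_ladder
#' @param plot draw with base graphics (default) or just return the curves.
#' @return invisibly, the `survival::survfit` object.
#' @export
plot_loglog <- function(records, variable = "prolonged", cutoff = 30,
                        plot = TRUE) {
  qcol <- paste0("quartile_", variable, "_", cutoff)
  g <- factor(records[[qcol]])
  sf <- survival::survfit(
    survival::Surv(time_years, event) ~ g, data = records)
  if (plot) {
    plot(sf, fun = "cloglog", col = seq_len(nlevels(g)),
         xlab = "Years (log scale)", ylab = "log(-log S(t))")
  }
  invisible(sf)
}
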