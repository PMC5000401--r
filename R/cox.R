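#' Model specification for the Cox ladder
#'
#' The four nested adjustment sets used for incident metabolic syndrome:
#' Model 1 adjusts for sex and age; Model 2 adds education, smoking and
#' family income; Model 3 adds weekly MVPA; Model 4 adds baseline waist
#' circumference. Ties are always handled with the Efron approximation
#' (annual checkups make event times heavily tied).
#'
#' @param variable exposure variable: `"total"`, `"prolonged"` or
#'   `"nonprolonged"`; `NULL` for a covariates-only model.
#' @param cutoff bout cut-off (10, 20 or 30 minutes) identifying the
#'   exposure columns.
#' @param level model level 1--4.
#' @param covariates optional explicit covariate column names, overriding the
#'   ladder set (used for small hand-built fits).
#' @return a `model_spec` list.
#' @export
model_spec <- function(variable = "prolonged", cutoff = 30, level = 3,
                       covariates = NULL) {
  if (!is.null(variable) &&
      !variable %in% c("total", "prolonged", "nonprolonged")) {
    stop("unknown exposure variable: ", variable, call. = FALSE)
  }
  if (!level %in% 1:4) stop("model level must be 1-4", call. = FALSE)
  structure(
    list(variable = variable, cutoff = cutoff, level = level,
         covariates = covariates, ties = "efron", reference = 1L),
    class = "model_spec"
  )
}

# Ladder covariate sets, in model-frame column names.
ladder_covariates <- function(level) {
  sets <- list(
    c("sex_female", "age"),
    c("sex_female", "age", "edu_college", "smoker_yes",
      "income_mid", "income_high"),
    c("sex_female", "age", "edu_college", "smoker_yes",
      "income_mid", "income_high", "mvpa_min_per_week"),
    c("sex_female", "age", "edu_college", "smoker_yes",
      "income_mid", "income_high", "mvpa_min_per_week", "baseline_waist_cm")
  )
  sets[[level]]
}

# Recode raw covariate columns to the numeric model frame. Income uses <4M
# JPY as the reference category (two indicators).
prepare_model_frame <- function(records) {
  mf <- records
  if ("sex" %in% names(records)) {
    mf$sex_female <- as.numeric(records$sex == "female")
  }
  if ("education" %in% names(records)) {
    mf$edu_college <- as.numeric(records$education == "college+")
  }
  if ("smoker" %in% names(records)) {
    mf$smoker_yes <- as.numeric(records$smoker == "yes")
  }
  if ("income" %in% names(records)) {
    mf$income_mid <- as.numeric(records$income == "4-8M")
    mf$income_high <- as.numeric(records$income == ">=8M")
  }
  mf
}

quartile_column <- function(spec) {
  paste0("quartile_", spec$variable, "_", spec$cutoff)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with the Efron tie correction
#' (Newton--Raphson, log-likelihood tolerance 1e-9, at most 100 iterations)
#' for the covariate set implied by `spec`. The exposure quartile enters as
#' three indicator terms against quartile 1. Standard errors come from the
#' observed information.
#'
#' @param records survival records (see [build_survival_records()]) or any
#'   `data.frame` with `time_years`, `event` and the covariate columns.
#' @param spec a [model_spec()].
#' @return a `cox_fit` object: coefficients, SEs, hazard ratios with 95% CIs,
#'   Wald p-values, partial log-likelihood, n, n_events, iterations and a
#'   convergence flag.
#' @export
fit_cox <- function(records, spec = model_spec()) {
  mf <- prepare_model_frame(records)
  covs <- if (!is.null(spec$covariates)) spec$covariates
          else ladder_covariates(spec$level)
  terms <- covs
  if (!is.null(spec$variable)) {
    qcol <- quartile_column(spec)
    if (!qcol %in% names(mf)) {
      stop("records lack exposure column ", qcol, call. = FALSE)
    }
    for (q in 2:4) mf[[paste0("Q", q)]] <- as.numeric(mf[[qcol]] == q)
    terms <- c(paste0("Q", 2:4), covs)
  }
  missing_terms <- setdiff(terms, names(mf))
  if (length(missing_terms) > 0) {
    stop("records lack covariate columns: ",
         paste(missing_terms, collapse = ", "), call. = FALSE)
  }
  for (tm in terms) {
    if (stats::var(mf[[tm]]) == 0) {
      stop("covariate '", tm, "' has zero variance", call. = FALSE)
    }
  }
  if (sum(mf$event) < 2) stop("fewer than 2 events", call. = FALSE)

  fml <- stats::as.formula(
    paste("survival::Surv(time_years, event) ~",
          paste(terms, collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = mf, ties = spec$ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("did not converge|infinite|out of iterations",
                conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  if (any(!is.finite(beta)) || any(abs(beta) > 10)) converged <- FALSE
  z <- stats::qnorm(0.975)
  structure(
    list(
      terms = names(beta),
      coef = unname(beta),
      se = unname(se),
      hr = unname(exp(beta)),
      ci_lower = unname(exp(beta - z * se)),
      ci_upper = unname(exp(beta + z * se)),
      p = unname(2 * stats::pnorm(-abs(beta / se))),
      loglik = fit$loglik[2],
      loglik_null = fit$loglik[1],
      n = fit$n,
      n_events = fit$nevent,
      iterations = fit$iter,
      converged = converged,
      spec = spec
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (Efron ties): n = %d, events = %d, %s\n",
              x$n, x$n_events,
              if (x$converged) sprintf("converged in %d iterations",
                                       x$iterations)
              else "DID NOT CONVERGE"))
  tab <- data.frame(term = x$terms, coef = round(x$coef, 4),
                    HR = round(x$hr, 3),
                    `95% CI` = sprintf("(%.3f-%.3f)", x$ci_lower, x$ci_upper),
                    p = signif(x$p, 3), check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Hazard ratios with Wald confidence intervals
#'
#' @param fit a converged [fit_cox()] result.
#' @param level confidence level.
#' @return `data.frame` with `term`, `hr`, `lower`, `upper`.
#' @export
wald_ci <- function(fit, level = 0.95) {
  if (!inherits(fit, "cox_fit")) stop("`fit` must be a cox_fit",
                                      call. = FALSE)
  if (!fit$converged) {
    stop("refusing to report HRs from a non-converged fit", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(
    term = fit$terms,
    hr = exp(fit$coef),
    lower = exp(fit$coef - z * fit$se),
    upper = exp(fit$coef + z * fit$se)
  )
}
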