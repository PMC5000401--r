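# Independent oracles for the bout engine and the Cox fitter. These check the
# rules literally, by enumeration over candidate intervals or grid search,
# and share no code with the package implementations.

# Random 1440-minute MET trace with block structure: alternating segments of
# sub-1.0, exactly-1.0, sedentary, light, MVPA, missing and per-minute-noise
# levels, so window/bout/period boundaries of every kind occur.
random_trace <- function() {
  met <- numeric(0)
  while (length(met) < 1440) {
    len <- sample(c(1:3, sample(1:90, 1)), 1)
    type <- sample(c("low", "one", "sed", "light", "mvpa", "miss", "noise"),
                   1, prob = c(.20, .13, .17, .15, .10, .10, .15))
    vals <- switch(type,
      low = round(runif(len, 0, 0.9), 1),
      one = rep(1.0, len),
      sed = round(runif(len, 1.0, 1.5), 1),
      light = round(runif(len, 1.6, 2.9), 1),
      mvpa = round(runif(len, 3.0, 6.0), 1),
      miss = rep(NA_real_, len),
      noise = round(runif(len, 0, 6), 1))
    met <- c(met, vals)
  }
  met[1:1440]
}

# Literal non-wear enumeration: from every start of a sub-1.0 run, walk right
# applying the rules one minute at a time (sub-1.0 or missing extends; 1.0
# extends only in runs of <= 2; anything else terminates); keep windows of
# span >= 60 that are not contained in another.
oracle_nonwear <- function(met) {
  cls <- ifelse(is.na(met), 0L,
                ifelse(abs(met - 1) <= 1e-3, 1L,
                       ifelse(met > 1, 2L, 0L)))
  n <- length(cls)
  anchors <- which(cls == 0L & c(2L, cls[-n]) != 0L)
  cand <- list()
  for (s in anchors) {
    ones <- 0L
    last_low <- s
    k <- s + 1L
    while (k <= n) {
      if (cls[k] == 2L) break
      if (cls[k] == 1L) {
        ones <- ones + 1L
        if (ones > 2L) break
      } else {
        ones <- 0L
        last_low <- k
      }
      k <- k + 1L
    }
    if (last_low - s + 1L >= 60L) {
      cand[[length(cand) + 1L]] <- c(s, last_low)
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(start = integer(), end = integer(), span = integer()))
  }
  m <- unique(do.call(rbind, cand))
  contained <- vapply(seq_len(nrow(m)), function(i) {
    any(m[, 1] <= m[i, 1] & m[, 2] >= m[i, 2] &
          (m[, 1] != m[i, 1] | m[, 2] != m[i, 2]))
  }, logical(1))
  m <- m[!contained, , drop = FALSE]
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start = m[, 1] - 1L, end = m[, 2],
             span = m[, 2] - m[, 1] + 1L)
}

oracle_worn <- function(met, windows) {
  worn <- !is.na(met)
  for (i in seq_len(nrow(windows))) {
    worn[(windows$start[i] + 1L):windows$end[i]] <- FALSE
  }
  worn
}

# Sedentary bouts via index differencing (split the sorted sedentary-minute
# indices wherever they jump).
oracle_sedentary <- function(met, windows) {
  worn <- oracle_worn(met, windows)
  idx <- which(worn & !is.na(met) & met <= 1.5 + 1e-6)
  if (length(idx) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  }
  br <- which(diff(idx) > 1L)
  starts <- idx[c(1L, br + 1L)]
  ends <- idx[c(br, length(idx))]
  data.frame(start = starts - 1L, end = ends, length = ends - starts + 1L)
}

# Literal greedy MVPA scan, minute by minute.
oracle_mvpa <- function(met, windows) {
  worn <- oracle_worn(met, windows)
  mv <- worn & !is.na(met) & met >= 3 - 1e-6
  res <- list()
  i <- 1L
  n <- length(met)
  while (i <= n) {
    if (!mv[i]) {
      i <- i + 1L
      next
    }
    used <- 0L
    last <- i
    k <- i + 1L
    while (k <= n && worn[k]) {
      if (mv[k]) {
        last <- k
      } else {
        used <- used + 1L
        if (used > 2L) break
      }
      k <- k + 1L
    }
    if (last - i + 1L >= 10L) {
      res[[length(res) + 1L]] <- c(i - 1L, last, last - i + 1L,
                                   sum(mv[i:last]))
    }
    i <- last + 1L
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(), end = integer(), span = integer(),
                      credited = integer()))
  }
  m <- do.call(rbind, res)
  data.frame(start = m[, 1], end = m[, 2], span = m[, 3], credited = m[, 4])
}

# Hand-coded Efron partial log-likelihood for one covariate, evaluated
# directly from its definition.
efron_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (t in unique(time[status == 1])) {
    D <- which(status == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sum_d <- sum(exp(x[D] * beta))
    sum_r <- sum(exp(x[R] * beta))
    ll <- ll + sum(x[D]) * beta -
      sum(log(sum_r - ((seq_len(d) - 1) / d) * sum_d))
  }
  ll
}

# Grid-search maximizer of the Efron partial likelihood (coarse pass over
# [-5, 5], then a fine pass around the coarse optimum).
grid_cox <- function(time, status, x) {
  coarse <- seq(-5, 5, by = 0.001)
  ll <- vapply(coarse, efron_loglik, numeric(1), time, status, x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.002, b0 + 0.002, by = 1e-5)
  fine[which.max(vapply(fine, efron_loglik, numeric(1), time, status, x))]
}

# Small single-covariate survival datasets (n <= 8) with interior partial-
# likelihood maxima: distinct times, censoring, and Efron-relevant event
# ties, binary and continuous covariates.
cox_fixtures <- function() {
  list(
    distinct_times = list(time = 1:6, status = rep(1, 6),
                          x = c(0, 1, 0, 1, 1, 0)),
    with_censoring = list(time = c(1, 1, 2, 3, 4, 5),
                          status = c(1, 0, 1, 1, 0, 1),
                          x = c(1, 0, 0, 1, 0, 1)),
    tied_events = list(time = c(1, 1, 1, 2, 2, 3),
                       status = c(1, 1, 0, 1, 1, 0),
                       x = c(1, 0, 1, 0, 1, 0)),
    continuous_x = list(time = 1:8,
                        status = c(1, 1, 0, 1, 1, 0, 1, 1),
                        x = c(0.5, -1.2, 0.3, 2.1, -0.7, 1.5, 0, -0.3)),
    heavy_tie = list(time = c(1, 1, 1, 1, 2),
                     status = c(1, 1, 1, 0, 1),
                     x = c(0, 1, 1, 0, 1)),
    tied_binary = list(time = c(1, 1, 2, 2, 2, 3, 3, 4),
                       status = c(1, 1, 1, 1, 0, 1, 0, 0),
                       x = c(1, 0, 1, 0, 1, 0, 1, 0)),
    alternating = list(time = 1:4, status = rep(1, 4), x = c(1, 0, 1, 0))
  )
}

fit_cox_single <- function(d) {
  rec <- data.frame(time_years = d$time, event = d$status, x = d$x)
  fit_cox(rec, model_spec(variable = NULL, covariates = "x"))
}

# One simulated analysis-ready cohort at survival scale (no epoch engine).
simulate_cohort <- function(n, seed, out_params = outcome_gen_params(),
                            cutoffs = 30) {
  cov <- generate_covariates(n, seed = seed)
  summ <- generate_activity_summaries(cov, seed = seed + 1L)
  exp <- build_exposures(summ, cov$sex, cutoffs = cutoffs)
  prim <- exp$exposures[exp$exposures$variable == "prolonged" &
                          exp$exposures$cutoff == max(cutoffs), ]
  visits <- generate_outcomes(prim, cov, out_params, seed = seed + 2L)
  mvpa <- data.frame(participant_id = summ$participant_id,
                     mvpa_min_per_week = summ$mvpa_min_per_week,
                     stringsAsFactors = FALSE)
  build_survival_records(visits, cov, exp$exposures, mvpa)
}
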