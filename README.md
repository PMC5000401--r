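# sedbouts

Tools for prospective accelerometer studies of **sedentary bout
accumulation and incident metabolic syndrome**. The package takes
minute-resolution MET intensity series and annual-checkup biomarker panels
and produces the full analysis a cohort paper reports: wear-time and bout
summaries, wear-adjusted exposures in sex-specific quartiles, Joint Interim
Statement 2009 syndrome classification, person-time, and nested Cox
proportional-hazards model ladders — plus a synthetic cohort generator with
known ground truth so the entire chain is testable without participant
data.

## What it computes

* **Epoch engine.** Non-wear detection (≥ 60 consecutive sub-1.0-MET
  minutes, allowing ≤ 2 consecutive minutes at exactly 1.0 MET), sedentary
  bouts (maximal uninterrupted runs at ≤ 1.5 METs during wear), bout
  accumulation into *prolonged* (≥ cut-off) vs *non-prolonged* time at
  10/20/30-minute cut-offs, MVPA periods (≥ 10 min at ≥ 3 METs with a
  2-minute cumulative interruption allowance), valid days (≥ 600 wear
  minutes) and analyzable participants (≥ 4 valid days).
* **Exposures.** Residual-method adjustment of sedentary time for wear
  time — adjusted value = residual + prediction at the cohort-mean wear
  time, so min/day units are kept, the mean is preserved and the adjusted
  variable is exactly orthogonal to wear time — followed by sex-specific
  quartiles (type-7 quantiles, ties to the lower quartile).
* **Outcome.** JIS-2009 classification (≥ 3 of 5 components, medication
  flags forcing blood-pressure/glucose/triglyceride components), baseline
  screening, person-time to first positive exam or censoring, incidence
  rates per 1000 person-years.
* **Models.** Cox PH with Efron ties: quartile indicators vs Q1 through a
  nested ladder (M1 sex+age; M2 +education, smoking, income; M3 +MVPA;
  M4 +waist), single-df interaction tests (age, sex, MVPA ≥ 150 min/wk),
  quartile trend tests, and sensitivity analyses (10/20-min cut-offs,
  stratification by baseline component count, exclusion of medicated
  participants).

See `vignettes/sedentary-bouts-methods.Rmd` for the full methods account.

## Worked example

Simulate a cohort at the design scale (430 participants), build exposures,
classify outcomes and fit the MVPA-adjusted model:

```r
library(sedbouts)

cov       <- generate_covariates(430, seed = 20)
summaries <- generate_activity_summaries(cov, seed = 21)
built     <- build_exposures(summaries, cov$sex, cutoffs = 30)
prolonged <- subset(built$exposures, variable == "prolonged")
visits    <- generate_outcomes(prolonged, cov, outcome_gen_params(), seed = 22)
mvpa      <- data.frame(participant_id = summaries$participant_id,
                        mvpa_min_per_week = summaries$mvpa_min_per_week)
records   <- build_survival_records(visits, cov, built$exposures, mvpa)

sum(records$event)        # 71 incident cases among 430 participants
incidence_rate(records)   # 58.3 per 1000 person-years

ladder <- fit_model_ladder(records, "prolonged", 30, levels = 3)
print(attr(ladder, "fits")$model3)
#> Cox PH fit (Efron ties): n = 430, events = 71, converged in 5 iterations
#>               term    coef    HR         95% CI        p
#>                 Q2  1.4727 4.361 (1.766-10.767) 0.001410
#>                 Q3  1.0644 2.899  (1.131-7.428) 0.026600
#>                 Q4  1.6804 5.368 (2.206-13.059) 0.000212
#>         sex_female -0.3552 0.701  (0.319-1.543) 0.377000
#>                age  0.0271 1.027  (0.995-1.061) 0.098400
#>        ...
```

Quartiles 2–4 of prolonged sedentary time show elevated hazards relative
to quartile 1, as built into the generator (true HRs 2.72/2.42/2.85; with
~18 events per quartile the log-HR standard error is ≈ 0.45, so single-run
estimates scatter widely around those values). The covariate rows behave
as generated: a modest age gradient, no MVPA effect.

The same chain runs from raw epoch data: `read_epoch_csv()` →
`process_epochs()` → `summarize_participants()` → `build_exposures()`, or
end to end via `run_pipeline()` (YAML-configurable; see
`pipeline_config()`), which writes all result tables plus a manifest with
the exclusion flow. A thin command-line front end with
`simulate` / `process` / `analyze` / `run-all` subcommands is installed at
`inst/cli/sedbouts.R`.

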