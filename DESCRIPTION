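Package: sedbouts
Title: Sedentary Bout Accumulation and Incident Metabolic Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Processes minute-resolution accelerometer MET series into
    wear-time, sedentary-bout and MVPA summaries (non-wear detection with a
    two-minute allowance, bout accumulation at 10/20/30-minute cut-offs),
    builds wear-time residual-adjusted exposures with sex-specific quartiles,
    classifies metabolic syndrome from the Joint Interim Statement 2009
    criteria, and fits nested Cox proportional-hazards model ladders with
    Efron tie handling for incident metabolic syndrome. Includes a synthetic
    cohort generator encoding the prospective-study structure (alternating
    sedentary/active bouts, annual checkups, proportional-hazards onset) so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
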