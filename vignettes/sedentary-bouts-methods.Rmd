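---
title: "From minute-level MET series to metabolic-syndrome hazard ratios: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From minute-level MET series to metabolic-syndrome hazard ratios: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedbouts)
```

`sedbouts` implements a complete analysis chain for prospective studies of
sedentary-bout accumulation and incident metabolic syndrome: accelerometer
epoch processing, exposure construction, outcome classification, and Cox
proportional-hazards modelling, together with a synthetic cohort generator
that makes the whole chain testable end to end without any participant data.
This vignette explains the models and rules, the tunable parameters and
their defaults, the numerical conventions, and what the synthetic generator
does and does not emulate.

## The epoch engine

The raw material is a per-participant, per-day sequence of minute epochs,
each carrying an activity intensity in METs (multiples of resting energy
expenditure). Epoch length is fixed at 60 s; minutes are indexed 0–1439 and
may be missing. Three detectors turn a day into summaries:

**Non-wear.** A non-wear window is a maximal run of at least 60 consecutive
minutes below 1.0 MET, allowing interior runs of at most two *consecutive*
minutes at exactly 1.0 MET. Any minute above 1.0 MET, or a third consecutive
1.0-MET minute, terminates the window, and windows must begin and end on
sub-1.0 minutes (so terminal allowance minutes are shed — without this rule
maximality would be ambiguous). Two allowance runs separated by a single
sub-1.0 minute each count separately; that is the literal reading of the
consecutive-minutes rule and is the convention implemented here.
"Exactly 1.0" is evaluated at the device's one-decimal precision with a
±0.001 tolerance after parsing. Missing minutes count as sub-1.0 — absent
data cannot certify that the device was worn.

**Sedentary bouts.** Sedentary behaviour is any worn minute at ≤ 1.5 METs.
A bout is a maximal uninterrupted run of such minutes: one minute above
1.5 METs, a non-wear window, a missing minute or the day boundary ends it
(bouts never cross midnight; the day is the unit of summary). Worn sub-1.0
minutes that fall outside a qualifying non-wear window are sedentary — the
definition is purely the ≤ 1.5 threshold during wear. Bout time is then
accumulated at a cut-off: time in bouts of at least 30 min is *prolonged*
sedentary time, the rest *non-prolonged*; 10- and 20-min cut-offs are
carried alongside for sensitivity analyses. By construction
prolonged + non-prolonged = total at every cut-off, and prolonged time is
non-increasing in the cut-off.

**MVPA periods.** Moderate-to-vigorous physical activity is ≥ 3.0 METs. A
period is an interval of span ≥ 10 min that starts and ends on MVPA minutes
and contains at most 2 cumulative minutes of worn non-MVPA activity. The
scan is greedy left-to-right: the current period extends until its 2-minute
interruption budget would be exceeded, then closes at the last MVPA minute.
The budget is cumulative per period, not per interruption — this mirrors the
National Cancer Institute's bout-detection convention for accelerometer
data, which this engine re-specifies. Allowance minutes count toward span
(qualification) but not toward *credited* MVPA minutes, since the analysis
covariate is time actually spent at ≥ 3 METs.

A day is valid with ≥ 600 wear minutes; a participant enters analyses with
≥ 4 valid days. Participant-level metrics are means over valid days only,
and weekly MVPA is 7 × mean daily credited minutes. All thresholds are
boundary-exact (60 vs 59, 600 vs 599, 30 vs 29, 10 vs 9), and the three
detectors are tested for exact agreement with independent brute-force
enumeration oracles on 10,000 random traces.

## Exposure construction

Wear time varies between participants and mechanically inflates sedentary
time, so each participant-level sedentary variable is adjusted by the
*residual method* familiar from nutritional epidemiology's energy
adjustment: regress the variable on mean daily wear time by ordinary least
squares (pooled over sexes — quartiles are sex-specific below, but nothing
indicates sex-specific adjustment, and pooling matches the residual-method
convention), then report residual + prediction at the cohort-mean wear
time. This keeps values on the min/day scale — published cut-points are
interpreted "for a participant with average wear time" — preserves the
cohort mean, and makes the adjusted variable exactly orthogonal to wear
time. Degenerate input (zero wear variance) is defined to have slope 0, so
adjustment is the identity. The operation is idempotent.

Adjusted values are split into sex-specific quartiles. Cut-points are the
25th/50th/75th linear-interpolation sample quantiles (R's default type 7);
a value exactly at a cut-point goes to the lower quartile. These two
conventions are arbitrary where ties and interpolation are concerned, but a
bit-exact documented rule is required for reproducibility. After labelling,
men's and women's groups are pooled into a single Q1–Q4 axis for modelling,
which is the usual arrangement when a results table has one quartile axis
with sex-specific boundaries.

## Outcome classification and person-time

Metabolic syndrome follows the Joint Interim Statement 2009 definition:
at least 3 of central obesity (waist ≥ 90 cm men / ≥ 85 cm women), elevated
blood pressure (SBP ≥ 130 or DBP ≥ 85 mmHg, or antihypertensive
medication), elevated fasting glucose (≥ 5.6 mmol/L or hypoglycemic
medication), low HDL-cholesterol (< 1.0 / < 1.3 mmol/L, men/women), and
hypertriglyceridemia (≥ 1.7 mmol/L or lipid-lowering medication). A missing
measurement is tolerated only when its medication flag already decides the
component; otherwise the record is a missing-data error and the participant
is excluded upstream, mirroring the usual covariate-completeness exclusion.

Person-time runs from the baseline examination to the first
metabolic-syndrome-positive examination or the last attended examination,
whichever comes first. The event date is the positive exam's date, not an
interval midpoint — interval-censored likelihoods are out of scope — and a
participant who skips a checkup but is positive at the next attended one
contributes an event at that observed exam. Participants positive at
baseline are excluded and counted. Days convert to years by 365.25;
incidence rates are 1000 × events / person-years.

## Survival models

Hazard ratios come from Cox proportional-hazards models with the exposure
quartile entered as three indicators against Q1, maximizing the partial
likelihood with the **Efron** tie correction (annual checkups concentrate
events on a few dates, where Efron is markedly less biased than Breslow).
Fitting is delegated to `survival::coxph` (Newton–Raphson, log-likelihood
tolerance 1e-9, up to 100 iterations); the test suite independently checks
the fitter against a literal hand-coded Efron partial likelihood maximized
by grid search on every small fixture dataset. Zero-variance covariates are
rejected before fitting; non-convergence and diverging coefficients
(|log HR| > 10, the monotone-likelihood signature) mark the fit as
non-reportable, and `wald_ci()` refuses such fits.

The adjustment ladder is nested: Model 1 sex + age; Model 2 adds education,
smoking and household income; Model 3 adds weekly MVPA; Model 4 adds
baseline waist circumference. Age enters continuously in years (the most
parsimonious reading when nothing fixes age bands); education and smoking
are binary; income is two indicators with < 4M JPY as reference (the
natural lowest-category reference, otherwise unstated). Effect modification
is probed with a single product term of the quartile ordinal score (1–4)
and the modifier — age, sex, or MVPA dichotomized at 150 min/week — giving
a 1-df Wald test; a single-df score-by-modifier term is what a summary
statement that "no interaction was significant" most plausibly refers to,
and a 3-df version is a trivial extension. Trend tests across quartiles use
quartile scores 1–4: a Cochran–Armitage-style score test for binary
characteristics, the linear-by-linear association statistic
((n−1)r²) with integer category scores for ordered categoricals, and the
least-squares slope test for continuous ones. Proportional hazards is
inspected graphically (`plot_loglog()` emits complementary log-log curves)
and nothing is asserted about it, since no numeric criterion is defined.

Sensitivity analyses re-derive the ladder at the 10/20-min cut-offs,
stratify by baseline component count (0–1 vs 2, the higher-risk group), and
refit after excluding participants on any baseline medication (a probe of
the reversibility concern: treated participants are likelier to regress).

## The synthetic cohort generator

The generator exists so every stage has inputs with known ground truth; it
encodes the study design rather than any participant data.

**Epoch traces.** Each day is an alternating renewal sequence of sedentary
and active bouts filling a 07:00–21:00 wear window (840 min — wear windows
must span ≥ 10 h so valid days are producible). Bout lengths are log-normal,
rounded up to whole minutes (≥ 1): no distributional form is dictated by
observation here; log-normal matches the right skew of published bout data
and is parameterized by its arithmetic mean. Defaults — sedentary mean
15 min (σ = 1.0), active mean 8 min (σ = 0.75), 5% of active bouts at MVPA
level — were chosen once so that derived quantities land near the study's
reported scale: roughly 65% of wear time sedentary, prolonged(30) time
centred near 170 min/day, and median weekly MVPA near 50 min. A
participant-level log-normal multiplier (σ = 0.4) on the sedentary bout
mean gives stable between-participant differences. Minutes outside the wear
window carry sub-1.0 MET values (the device keeps recording on the
nightstand), so non-wear detection recovers the designed window exactly;
the default sedentary MET range starts at 1.0 for the same reason — sub-1.0
values are reserved for the non-wear signal. With probability 0.15 a day
gets a midday non-wear gap (mean 90 min, ≥ 60 so it is detectable).

**Covariates.** Sex (12.5% women), age uniform on 40–64, ~60% college
education, ~32% smokers, income 12/62/26% across the three bands — marginal
mixes matching a predominantly male office-worker cohort.

**Outcomes.** Latent onset time is exponential with hazard
h₀ · exp(lp), where lp combines the true quartile log-HRs of the
participant's *generated* prolonged(30) exposure (so measurement-error
studies can be layered later), a sex effect (−0.2 for women), an age effect
(0.02/year, centred at 52), and optionally a sex-by-quartile interaction
for power studies. Defaults: quartile HRs 2.72/2.42/2.85 and
h₀ = 0.031/year, tuned so the expected 3-year cumulative incidence is ~19%
(the design scale of 83 events in 430 participants): with mean relative
hazard ≈ 2.25 across quartiles, h₀ = −log(1 − 0.19)/(2.25·3). Onset is
observed at the first annual checkup at or after it, producing the heavy
event-time ties the Efron correction is there for. Onset is absorbing: the
syndrome is clinically reversible, but the estimand is first occurrence, so
reversals are irrelevant and not modelled. Biomarker panels are constructed
by inverting the classification: a target component count is chosen (0–2
before onset — every baseline panel classifies negative, matching the
cohort-entry criterion — and 3–5 from onset), the affected subset is drawn
uniformly, and values are drawn at least one measurement unit clear of each
threshold (0.1 mmol/L, 1 mmHg, 0.5 cm) so classification round-trips
exactly despite rounding.

**Participant-level shortcut.** For survival-scale simulations the epoch
engine is unnecessary, so `generate_activity_summaries()` draws
prolonged(30) and non-prolonged(30) time directly from independent
sex-specific log-normals whose quartiles sit near the published cut-offs
(men 106.7/165.5/269.2, women 65.1/122.7/195.4 min/day), with wear time
normal around 846 min/day. Independence of the two components is the
simplest structure consistent with a null non-prolonged association. One
consequence is worth stating plainly: total sedentary time is the sum of
the two components, so its quartiles are substantially correlated with
prolonged time's (r ≈ 0.7 at these spreads), and when prolonged time truly
carries hazard ratios of 2.4–2.9 the total-time quartiles inherit a
confounded association. At n = 2000 this is large relative to the standard
error, so confidence intervals for total-time quartiles do *not* cover 1 at
the nominal rate — the corresponding acceptance check fails honestly, and
no realistic variance configuration avoids it while keeping the published
prolonged-time spread. An observed null for total sedentary time at n = 430
is compatible with wide intervals, not with true independence.

**What the generator does not emulate:** seasonal and weekday/weekend
structure, posture (sitting vs standing at equal METs), raw tri-axial
acceleration and the device's MET-estimation algorithm, syndrome remission,
loss to follow-up patterns, and real covariate–exposure confounding beyond
the built-in effects. Passing tests therefore demonstrate that the
*computational chain* is correct under the declared statistical structure,
not that the epidemiological findings generalize.

## Numerical conventions and problem sizes

MET thresholds are compared with a 1e-6 tolerance around the one-decimal
input grid (values never sit closer than 0.05 to a threshold, so this only
absorbs float parsing). Quantiles are type 7; ties go down. Cox
convergence is 1e-9 on the log-likelihood; the grid-search oracle uses a
0.001 coarse / 1e-5 fine grid on [−5, 5]. The test suite runs the oracle
equivalence at 10,000 random traces, parameter recovery at 200 replicates
of n = 2000 (three quartile terms each), and interaction-test calibration
at 500 replicates of n = 600 — sizes at which binomial simulation error is
comfortably inside the asserted bands. The acceptance script simulates the
design scale itself: 430 participants × 10 days × 1440 minutes through the
full pipeline.

## Known limitations

Epoch lengths other than 60 s, imputation of missing epochs, bouts spanning
midnight, interval-censored or competing-risks formulations, frailty
models, and formal proportional-hazards tests are all out of scope. The
non-wear allowance follows the literal consecutive-run reading noted above;
devices or macros implementing a different allowance bookkeeping will
disagree on contrived traces. Hazard-ratio estimates at the design scale
(n = 430, ~80 events) carry standard errors of ~0.3 on the log scale;
single-run numbers from the acceptance script scatter accordingly around
the generator's truth.
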