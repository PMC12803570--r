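---
title: "Validating type 2 diabetes outcomes microsimulations"
author: "t2dsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating type 2 diabetes outcomes microsimulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dsim)
```

# The model

`t2dsim` implements a probabilistic, discrete-time illness–death
microsimulation for people with type 2 diabetes, in the tradition of the
UKPDS Outcomes Model: a set of linked parametric annual equations estimates
the likelihood of macrovascular events (myocardial infarction, stroke,
ischemic heart disease, heart failure), cardiovascular and
non-cardiovascular death, and the annual progression of clinical risk
factors. Each participant is carried through annual cycles; within a cycle
the event and death equations are evaluated in random order, each firing by
an independent uniform draw against its cycle probability; fired events
update the patient's state and hence later cycles' hazards.

Crucially, the package separates the *engine* from the *equations*. The 13
published UKPDS-OM2 equations are peer-reviewed and freely available but
their coefficient values are not reproduced here; the engine consumes any
coefficient file in the documented JSON format
(`inst/extdata/coefficients-schema.json`), admitting exponential, Weibull
and Gompertz proportional-hazards baselines and annual logistic models for
events and deaths, and a linear-autoregressive family for risk-factor
progression (`next = intercept + slope × current + drift × duration`,
richer forms being a configuration extension point). Covariate centering is
expressed in the coefficient file as affine pre-transforms, keeping the
engine transform-free. The shipped set
(`illustrative_coefficients()`) is clearly labelled synthetic: its
magnitudes are clinically plausible (e.g. annual MI hazard about 1.8% at
the covariate centres, rising about 12% per HbA1c percentage point) but it
is **not** the published model, and nothing in the package's validation
logic depends on its specific values.

## Cycle mechanics and numerical choices

Several behaviours of the published model family are under-determined by
its descriptions; the package fixes them as follows and treats each as a
deliberate design choice:

* **Evaluation order** is a fresh uniformly random permutation of the
  event/death equations *every cycle* (not once per participant). A
  property test confirms each equation occupies each position with
  frequency 1/k.
* **Within-cycle conflicts**: a fatal outcome — a death equation firing, or
  an event drawn fatal by its case-fatality term — ends the cycle
  immediately. Nonfatal events earlier in the permutation still count;
  later ones do not. The random order makes this rule unbiased on average.
* **Fractional horizons** (e.g. a 3.2-year median follow-up) are simulated
  as `floor(horizon)` full cycles plus one partial cycle whose hazard is
  integrated over the shortened interval. Because the integrated hazard is
  exact, two half-cycles compose to precisely one full cycle; a test pins
  the partial-cycle death probability to its closed form.
* **First events**: each event equation is evaluated until its first firing
  per replication. Mortality consequences of an earlier event are carried
  by the death equations' event-flag covariates (e.g. `event_mi`), not by
  re-firing the event equation. Participants with a prior event named in an
  equation's `excluded_if_prior` (ischemic heart disease, heart failure)
  never experience that endpoint and are excluded from its numerator *and*
  denominator, mirroring the first-event-only convention of the published
  model.
* **Composites** are derived, not simulated: MACE-3 is the union of CV
  death, MI and stroke; MACE-4 adds the unstable-angina proxy. The model
  family has no dedicated unstable-angina equation, so `ua_fraction`
  attaches a proxy sub-probability to any event equation; it defaults to 0
  (off), a documented limitation rather than a hidden assumption.
* **Reproducibility**: per-participant RNG substreams are derived by
  hashing `(seed, participant id)`, with all replications drawn from that
  stream, so results are bit-identical across runs and independent of
  cohort row order. Replications default to 200 — enough that the
  across-replication event frequency (the patient-level predicted risk)
  resolves to 0.5% steps, while keeping full-trial-scale runs in seconds.

# Cohort preparation

The cohort dialect is one CSV row per participant-year (year 0 =
baseline). Risk factors and units: weight (kg), HDL- and LDL-cholesterol
(mmol/L), systolic blood pressure (mmHg), HbA1c (%), heart rate (bpm),
white cell count (10⁹/L), haemoglobin (g/dL), eGFR (mL/min/1.73 m²), plus
smoking, atrial fibrillation, peripheral arterial disease and albuminuria
as 0/1 flags; demographics are age, sex, race/ethnicity, diabetes duration
and height; eight prior-event categories (ischemic heart disease, heart
failure, amputation, blindness, kidney failure, MI, stroke, foot ulcer)
are flagged at baseline. Because exact prior-event dates are typically not
recorded in trial databases, all prior events are set to have occurred one
year before baseline.

Imputation follows the conventions used when entering trial data into this
model family, with the gaps filled by explicit choices:

* **Admissible ranges.** Every continuous factor has a prespecified
  `[min, max]` window (`default_factor_limits()`, e.g. HbA1c 4–15%,
  SBP 70–250 mmHg); the published limits are not printed anywhere public,
  so the defaults are conventional clinical plausibility windows and fully
  configurable. Observed values *outside* the window are treated as missing
  and re-imputed — not clamped — since a recorded HbA1c of 99 is more
  plausibly an artefact than a true extreme. Values *generated* by
  progression equations are clamped.
* **Mean substitution** covers the low-missingness factors (HbA1c, SBP,
  weight, heart rate, eGFR, each typically below 5% missing): the
  replacement is the mean of in-range observed values among participants of
  the same sex and 10-year age band (<55, 55–64, 65–74, ≥75 — the
  adjustment granularity is not defined by the model's documentation, so
  the bands are configurable), falling back to the whole-study mean and
  finally to a configured population average if a factor is missing for an
  entire study.
* **Stratified imputation** covers HDL, LDL and haemoglobin, which in
  practice are missing at high rates and not at random. Strata are
  sex × age band × prior-cardiovascular-event status, with a fallback chain
  that drops the prior-event split, then the age band, then uses the whole
  study; each missing cell is drawn from the empirical distribution of
  in-range observed values in its stratum (a mean option exists),
  deterministically given the seed, with imputed cells flagged. Stratified
  single imputation does not eliminate the risk of artificially inflating
  accuracy under missingness-not-at-random — a limitation inherited from
  the procedure itself; multiple imputation is out of scope.
* **Follow-up fill-in** populates missing annualized values by running the
  progression equations forward from the most recent available value — not
  from baseline — so observed mid-trial measurements anchor later years.
  Observed values are never overwritten.
* **Booleans** (smoking and the comorbidity flags): whether these were
  imputed in practice is not documented; the package carries the last
  observation forward and defaults a wholly missing flag to 0.

# The validation battery

* **Accuracy**: per-arm first-event counts (mean across replications) and
  proportions, against observed counts; the simulated relative risk
  (active/placebo proportion ratio) against the observed unadjusted Cox
  hazard ratio (Efron ties, Wald 95% CI). Report tables round proportions
  to one decimal percent and ratios to two decimals, half-up.
* **Calibration**: deciles of predicted risk with observed proportions; the
  slope is the coefficient of logit(pred) in a logistic regression of the
  outcome, and the intercept is fitted with the slope fixed at 1
  (logit(pred) as offset) — the standard recalibration framework.
  Predictions are clipped to [1e-6, 1−1e-6]; constant predictions leave
  the slope undefined and flagged rather than fabricated.
* **Brier score** at the fixed horizon, on participants who either had the
  event by the horizon or were followed event-free to it; participants
  censored early are excluded (the simple fixed-horizon convention —
  inverse-probability-of-censoring weighting is a possible extension).
* **Harrell's C**: a pair is comparable when the shorter observed time
  belongs to a subject with the event (tied times: when exactly one has the
  event); risk ties count ½. The implementation is checked against
  exhaustive pair enumeration on hand instances and against
  `survival::concordance` on tie-free data.
* **Predicted risk** per participant is the across-replication event
  frequency from the engine — patient-level "simulated rates" — rather
  than an analytic expectation; `predict()` offers the analytic
  single-endpoint risk (no competing mortality) as a cheap upper-bound
  summary.
* **Subgroups**: count summaries by age (<65 vs ≥65, the boundary used in
  trial sensitivity analyses, configurable), sex, and prior-CV-event
  status; subgroup counts provably add to the overall counts.

# The synthetic trial generator

`cohort_profile()` ships TECOS- and EXSCEL-shaped profiles: arm sizes
7332/7339 and 7356/7396; prior-ASCVD prevalence 100% and 73.1% (every
ASCVD-flagged participant carries at least one of prior MI, stroke or
ischemic heart disease); follow-up drawn uniformly over the published
interquartile ranges (2.3–3.8 and 2.2–4.4 years), which lands the medians
near the published 3.0 and 3.2 years; and missing-not-at-random rates of
19.8% (HDL), 25.6% (LDL) and 39.7% (haemoglobin), implemented as a
logistic missingness model on the factor's own value (default −0.5
log-odds per SD, lower values more often missing) whose intercept is
calibrated so the marginal rate hits its target. Baseline marginals are
plausible type 2 diabetes values (HbA1c lognormal around 7.5%, SBP normal
around 135 mmHg, modest Gaussian-copula correlation among cardiometabolic
factors); the real trials' baseline tables are not public in this form, so
the marginals are illustrative *by design* and none of the package's
acceptance properties depend on their specific values.

What passing self-validation shows — and what it does not. The generator
draws continuous-time event times from proportional-hazards equations
evaluated at the (pre-mask, ground-truth) baseline state. When the
generating and simulating models coincide and factors are constant, the
engine's discrete annual incidence `1−(1−p)³` with `p = 1−e^{−h}` equals
the generator's continuous incidence `1−e^{−3h}` *exactly*, so the master
self-validation test (5 000 per arm, null arm effect) recovers relative
risk 1, calibration slope 1 and intercept 0 within Monte Carlo error, and
an informative Brier score — demonstrating the pipeline is internally
consistent, not that any particular coefficient set is externally valid.
When the generator draws multiple endpoints independently but the engine
applies competing mortality, engine risks are slightly conservative; the
README example shows this as a small positive calibration intercept. Real
trial data differ from the generator in ways the tests therefore cannot
probe: correlated endpoint processes, informative censoring,
measurement error, and covariate distributions far from the profiles.

# Problem sizes and runtime

The test suite exercises hand instances (≤20 subjects) against brute-force
oracles; the engine's analytic anchor at 20 000 replications of a
constant-hazard participant; parameter recovery (true hazard ratio 0.9) and
missingness recovery at full trial scale (14 752 and 14 671 participants);
and the master self-validation at 5 000 per arm with 200 replications.
These sizes keep the entire suite under a minute on one CPU while leaving
Monte Carlo standard errors small enough for 3-SE assertions to be
meaningful.

# Known limitations

* The shipped coefficients are illustrative; reproducing the published
  model requires its published coefficient file.
* Recurrent events are not simulated; the engine targets first-event
  validation quantities.
* The unstable-angina component of MACE-4 is a configurable proxy, off by
  default.
* Brier/calibration use the fixed-horizon convention without censoring
  weights; competing-risks estimators and time-dependent concordance are
  out of scope, as are costs, QALYs and lifetime extrapolation.
* Recalibration (re-estimating equation coefficients against new data) is
  deliberately not performed — the package measures external validity, it
  does not repair it.
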