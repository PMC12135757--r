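---
title: "Calibrating a wearable PM monitor and analysing a hay-soaking cross-over trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating a wearable PM monitor and analysing a hay-soaking cross-over trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmcal)
```

## The problem

Low-cost optical particulate (PM) sensors make personal exposure
assessment affordable — for example on the halter of a horse, where hay
dust in the breathing zone drives equine asthma — but they cannot be used
raw. Optical scattering responds to the aerosol's composition and size
distribution, so against a gravimetric-equivalent reference instrument a
unit calibrated for ambient urban aerosol may be off by large factors on
coarse organic dust. Two obstacles complicate a chamber calibration:

1. the reference instrument (a tapered element oscillating microbalance,
   TEOM) responds slowly, so fast and slow instruments can only be
   compared when the chamber is quasi-steady, and
2. the reference's response lags the optical sensors by several minutes,
   so matched averaging windows must be lag-aligned.

`pmcal` implements the full chain: quasi-steady-state screening, lag
estimation, per-unit and averaged-unit linear calibration with precision
diagnostics, application of the calibration to raw field logs, windowed
exposure averaging, and lognormal repeated-measures modelling of a
cross-over feeding trial (dry vs soaked hay). Seeded generators emulate
both experiments so every stage is testable without field data.

## Steady-state screening and lag alignment

Reference data are averaged to 1-min means (a minute needs at least 75%
of its expected samples — 9 of 12 at 5-s cadence — to count; the
completeness rule prevents single-sample minutes from steering the
screening). An interval qualifies as quasi-steady when the coefficient of
variation (sample SD over mean) of the minute means stays below 1% over
at least 5 min. Maximal qualifying runs are reduced to consecutive,
non-overlapping 5-min reporting intervals from the run's start: a
deterministic rule that maximises usable data while keeping regression
observations disjoint (overlapping windows would pseudo-replicate).

The reference lag is estimated by cross-correlating the fast comparison
monitor with the reference over integer minute lags 0–15 and taking the
Pearson-correlation argmax, ties resolved toward the smaller lag
(parsimony). The sign convention is fixed everywhere: *the reference
lags*; alignment therefore shifts the fast instruments' averaging window
*earlier* by the lag. Sub-minute lag refinement and deconvolution of the
reference response are out of scope.

```{r lag}
sim <- simulate_colocation(colocation_config(seed = 42))
estimate_lag(resample_to_minutes(sim$teom$pm2_5),
             resample_to_minutes(sim$comparison$pm2_5))
```

## Calibration and precision

For each steady interval the lag-aligned 5-min means of the three
wearable units are matched to the reference mean. Calibration is ordinary
least squares with the reference as the dependent variable:
`reference = beta * raw + alpha`. Alongside each per-unit fit, a
*universal* model is obtained by regressing on the across-unit mean
predictor — a fresh regression, not an average of per-unit coefficients —
giving one formula applicable to any unit of the family.

Reported diagnostics follow sensor-evaluation convention:

* **RMSE** is `sqrt(SSE/n)` (population form). The `n - 2` form differs
  by ~3% at n near 30; the convention is recorded in the serialised model
  (`rmse_convention = "sse_over_n"`).
* **Pooled inter-unit CV** is the root-mean-square of the per-interval
  CVs (sample SD across unit means over their mean), in percent.
* **Pairwise Pearson r** between unit interval means; a constant unit
  yields an undefined (missing) entry.
* Residual normality is checked with the Shapiro–Wilk test
  (delegated to `stats::shapiro.test`).

Corrections are affine, so window means may be corrected directly.
Negative corrected values are floored at zero only at the reporting
(window-mean) stage, never per sample, preserving linearity on the
regression scale.

```{r calibration}
fit <- calibrate_colocation(sim, "pm2_5")
fit$models$averaged
fit$precision
```

Temperature/RH covariates and PM1 are deliberately excluded: the chamber
runs under a tight temperature and humidity range, and the PM1 channel
has no reference against which a correction could be derived.

## The exposure trial model

In the cross-over trial every horse is measured under both treatments
(dry first, then soaked — matching the original design, which did not
randomise order), so each horse is its own control. Raw logs are
corrected through the universal calibration and averaged over two windows
from the moment forage is offered: *short* (first 20 min, the eating
peak) and *extended* (the full 8 h).

Concentration data of this kind are multiplicative, so the models are
linear mixed models on the natural log of the window mean — the standard
equivalent of a "repeated-measures generalised linear model under a
lognormal assumption". The random structure is a horse-level random
intercept; with two occasions per horse this coincides with a
compound-symmetry repeated-measures covariance. Estimation is REML with
Satterthwaite denominator degrees of freedom (a small-sample-appropriate
choice; the df method is otherwise an open modelling decision).
Least-squares means and their 95% confidence limits are exponentiated
back to concentration scale, where they estimate geometric-mean-like
exposures. Pairwise cell comparisons in the treatment-by-duration model
are Tukey-adjusted; a single two-level comparison reduces to the
unadjusted test. Zero window means (possible after flooring) are replaced
by 0.1 ug/m^3 before the log transform, with a logged count.

```{r trial}
trial <- simulate_feed_trial(trial_config(seed = 7))
an <- analyze_feed_trial(trial, list(pm2_5 = fit$models$averaged))
summary(an$treatment_fits$pm2_5.extended)
percent_reduction(an$treatment_fits$pm2_5.extended)
```

`percent_reduction()` is `100 * (1 - lsmean_soaked / lsmean_dry)`.

## What the generators emulate — and what they do not

The generators' defaults *are* the study conditions the pipeline is
validated against; they are not tuning knobs.

**Chamber generator.** The true concentration path is a sequence of ten
plateaus (10 min each, default levels 5–155 ug/m^3 for PM2.5 and
55–2450 ug/m^3 for PM10, inside the instruments' working ranges) joined
by 3-min linear ramps. The reference observes this path through a pure
4-min delay plus a symmetric 2-min moving average, at 1-min cadence with
0.5% lognormal noise. The smoothing is deliberately zero-phase: a causal
first-order filter would add its own ~1 min phase delay on top of the
configured delay, making the configured lag unrecoverable; with symmetric
smoothing the configured delay is exactly the net lag that
cross-correlation should find. Each wearable unit reports
`max(0, (true - alpha_i)/beta_i) * exp(eps)` every 5 s with a 5%
noise CV, using the published per-unit coefficients as generating
sensitivities. The default PM10 plateau levels are chosen so that the
inverted raw PM10 stays above raw PM2.5 with at least a 25% margin
(about 3.5 SD of the 5-s ratio noise): the wearable record invariant
`pm1 <= pm2_5 <= pm10` is enforced by construction, and levels violating
the margin would let that clamp silently overwrite the generating model
at low plateaus.

**Trial generator.** Each horse draws one random effect
`b_h ~ N(0, 0.35^2)` on the log scale, shared across treatments and size
fractions (horse behaviour drives exposure to both fractions); each
horse-treatment-metric cell adds independent `N(0, 0.25^2)` residuals to
the log window means. The true path is piecewise two-level — the 20-min
eating peak at `m20`, then the level that makes the 8-h mean come out at
`m8` exactly, floored at 0.5 ug/m^3 — rather than a mechanistic eating
model: only the two reported windows are analysis targets, and the
two-level profile hits both in expectation. Logs are emitted in *raw*
sensor units by inverting the universal calibration, so the analysis
pipeline must apply a calibration to recover truth. The between-horse and
residual SDs are this package's choice (the source experiment does not
report log-scale variance components); 0.35/0.25 give window means
spreading over roughly a 2–4-fold range across horses, typical of
personal dust exposure data.

**Known gaps between simulation and reality.** Sensor error is modelled
as white multiplicative noise, so it largely averages out of 5-min means
and the synthetic calibration r^2 (~0.999) is far higher than the 0.86–0.94
observed on real hay dust, where residual scatter comes from
aerosol-dependent unit response, not white noise. For the same reason the
pooled inter-unit CV (~10%) sits below the reported 13–14%. Passing the
recovery suite therefore demonstrates correctness of the estimators under
the stated statistical model, not field performance of any physical
sensor. Hay agitation physics, chamber airflow, temperature/RH dynamics,
and GPS behaviour are not simulated.

## Numerical and design choices

* Timestamps are timezone-naive local time (single-site studies),
  represented as UTC POSIXct; the log dialects print ISO-8601 seconds.
* The log writer uses the shortest decimal representation that parses
  back to the identical double, so read/write is a true round trip and
  repeated rewrites are byte-stable.
* Out-of-order log records are sorted with a warning (SD-card field logs
  commonly contain boot-time rewinds); duplicate timestamps are an error
  (ambiguous).
* Missing GPS fields are carried as absent, never as zero.
* CV uses the sample SD (n − 1). Lag ties break toward the smaller lag.
  Interval matching drops an interval when any instrument is missing more
  than 25% of its expected samples, with a logged reason.
* Mixed-model cells with zero variance (noise-free limits) are handled by
  `lme4`'s boundary fits; tests assert point estimates there, not
  standard errors.
* Reproducibility: every generator takes an integer seed and restores the
  caller's RNG state; `write_simulation()` records seed, config hash and
  file list in a JSON manifest.

Problem sizes used throughout the test and acceptance material — a
ten-plateau chamber run (~2 h of simulated time), ten-horse trials, and
200 replicate trials for recovery summaries — are the package's chosen
defaults for desk-scale validation of the estimators.

## Interface note

The package is a library, not a shell tool: the exported functions
(`simulate_colocation()`, `calibrate_colocation()`,
`simulate_feed_trial()`, `analyze_feed_trial()` and the lower-level
operations they compose) are the intended entry points, with
`scripts/acceptance.R` as a worked end-to-end driver. Structured-log
output (dropped intervals, floored means, excluded horses) is emitted via
R conditions so callers can capture or sink it.

## Limitations

The mixed model assumes the horse effect and residuals are normal on the
log scale; no unstructured repeated-measures covariance is offered (with
two occasions per horse it would not be identifiable apart from the
random intercept anyway). The lag estimator returns integer minutes only.
The universal calibration presumes the units being averaged are the units
that will be deployed; applying it to a new unit assumes exchangeability
with the calibrated family.
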