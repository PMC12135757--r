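# pmcal

Calibration of wearable low-cost optical particulate-matter (PM) monitors
against a slow-response reference instrument, and analysis of
breathing-zone PM exposure trials — motivated by equine asthma, where the
dust a horse inhales while eating hay is the exposure of interest and a
halter-mounted optical monitor is the practical way to measure it.

Low-cost optical sensors respond strongly to aerosol composition: on
coarse organic hay dust they can underestimate mass concentration by
large factors, so raw readings must be corrected against a
gravimetric-equivalent reference (TEOM). Two features of that comparison
drive the package design: the reference responds slowly, so instruments
can only be compared during quasi-steady chamber conditions, and the
reference *lags* the optical sensors by minutes, so matched averaging
windows must be lag-aligned.

## What it computes

**Calibration side.** From co-located logs, the pipeline

1. averages reference data to 1-min means and flags quasi-steady-state
   intervals by rolling coefficient of variation (CV < 1% over at least
   5 min), reduced to disjoint 5-min reporting intervals;
2. estimates the reference response lag `k` as the argmax over integer
   minutes of the Pearson correlation `cor(comparison(t), reference(t + k))`;
3. matches lag-aligned 5-min means across instruments and fits, per unit
   and for the across-unit average ("universal" model), the ordinary
   least-squares calibration

   `reference = beta * raw + alpha`

   with r², RMSE = √(SSE/n), slope p-value, and Shapiro–Wilk residual
   normality;
4. reports inter-unit precision: pooled CV (root-mean-square of
   per-interval SD/mean across units) and pairwise Pearson correlations.

**Trial side.** For a complete cross-over feed trial (each horse measured
under dry and soaked hay), raw logs are corrected through the calibration
and averaged over the first 20 min after forage is offered (short window)
and the full 8 h (extended window). Treatment and
treatment-by-duration effects are estimated with linear mixed models on
log window means — `log(conc) ~ treatment (+ duration + interaction) +
(1 | horse)` — via REML with Satterthwaite df; back-transformed
least-squares means estimate geometric-mean exposures, pairwise cell
comparisons are Tukey-adjusted, and
`percent_reduction() = 100 * (1 - lsmean_soaked / lsmean_dry)`.

Seeded generators (`simulate_colocation()`, `simulate_feed_trial()`)
emulate both experiments — plateau-structured chamber concentrations, a
4-min lagged and smoothed reference, per-unit sensitivity bias, and
lognormal per-horse exposures with an eating peak — so the full pipeline
runs and is tested without any field data.

## Worked example

```r
library(pmcal)

sim <- simulate_colocation(colocation_config(seed = 42))
fit <- calibrate_colocation(sim, "pm2_5")
fit
#> PM2.5 co-location calibration: 16 steady segments, 15 matched intervals
#> Reference response lag: 4 min (peak Pearson r = 0.9999)
#> Convention: the reference lags the fast instruments; alignment shifts fast-instrument windows earlier.
#> unit       r^2      RMSE         slope      intercept
#> BB1        1.000    0.756        4.456      -4.934
#> BB2        1.000    0.542        4.147      -2.633
#> BB3        1.000    0.739        3.601      -2.581
#> averaged   1.000    0.349        4.037      -3.322
#> PM2.5 inter-unit precision over 15 matched intervals
#>   pooled CV: 9.63%
#>   pairwise Pearson r: min 0.9997, max 0.9999
```

The generator built the three units with sensitivities (4.48, 4.16, 3.60)
and offsets (−5.17, −2.82, −2.58), and the fitted rows recover them; the
universal slope ~4.04 says raw readings underestimate PM2.5 roughly
4-fold on this aerosol. The detected lag is the 4 min the generator
injected.

```r
trial <- simulate_feed_trial(trial_config(seed = 7))
an <- analyze_feed_trial(trial, list(pm2_5 = fit$models$averaged))
an$treatment_fits$pm2_5.extended
#> PM2.5 extended-window exposure model (10 horses, cross-over)
#>   lsmeans (back-transformed, 95% CI):
#>     dry                  80.0  [51.9, 123.3] ug/m^3
#>     soaked               30.8  [20.0, 47.4] ug/m^3
#>   p-values: treatment = 4.712e-06
#>   log-scale SDs: horse 0.574, residual 0.221
#>   soaked vs dry reduction: 61.5%
```

The trial generator's 8-h geometric means were 76 (dry) and 31 (soaked)
ug/m^3; the mixed model recovers 80.0 and 30.8 from this 10-horse
replicate, and the estimated reduction from soaking hay is 61.5%
(generating value 59.2%). `plot()` on a fit draws the least-squares means
with CI whiskers over the individual horse-day points;
`an$duration_fits$pm2_5` adds the duration and interaction tests.

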