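# Shared fixtures, all built in code.

t0 <- as.POSIXct("2023-03-01 08:00:00", tz = "UTC")

# Minute-mean table in the shape resample_to_minutes() returns.
mk_minutes <- function(values, start = t0, n_samples = 12L, complete = TRUE) {
  data.frame(minute_start = start + (seq_along(values) - 1L) * 60,
             value = values,
             n_samples = n_samples,
             complete = complete)
}

# Wearable record frame with a prescribed pm2_5 channel; other channels
# chosen to satisfy the record invariants.
mk_wearable_df <- function(pm2_5, start = t0, cadence_s = 5, pm10 = 2 * pm2_5) {
  n <- length(pm2_5)
  data.frame(timestamp = start + (seq_len(n) - 1L) * cadence_s,
             pm1 = 0.5 * pm2_5, pm2_5 = pm2_5, pm10 = pm10,
             n_gt_0_3 = round(200 * pm2_5), n_gt_0_5 = round(60 * pm2_5),
             n_gt_1_0 = round(10 * pm2_5), n_gt_2_5 = round(2 * pm2_5),
             n_gt_5_0 = round(0.5 * pm2_5), n_gt_10 = rep(0, n),
             temp_c = rep_len(22.4, n), rh_pct = rep_len(18, n),
             lat = rep_len(NA_real_, n), lon = rep_len(NA_real_, n))
}

mk_wearable <- function(pm2_5, unit_id = "BB1", ...) {
  pm_series(unit_id, "wearable", "both", mk_wearable_df(pm2_5, ...))
}

mk_value_series <- function(values, kind = "teom", unit_id = "T1",
                            size_fraction = "pm2_5", start = t0,
                            cadence_s = 60) {
  pm_series(unit_id, kind, size_fraction,
            data.frame(timestamp = start + (seq_along(values) - 1L) * cadence_s,
                       value = values))
}

# Independent closed-form OLS oracle (normal equations).
ols_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  b <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  a <- my - b * mx
  res <- y - (a + b * x)
  list(slope = b, intercept = a,
       r2 = 1 - sum(res^2) / sum((y - my)^2),
       rmse = sqrt(mean(res^2)))
}

# Noise-free co-location configuration (no lag, no smoothing) for exact
# parameter-recovery checks.
noiseless_config <- function(unit_params = default_unit_params(), ...) {
  colocation_config(unit_params = unit_params,
                    teom_lag_min = 0, teom_smoothing_min = 0,
                    noise_cv = 0, teom_noise_cv = 0, comparison_noise_cv = 0,
                    ...)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# Exact universal calibration models (published averaged coefficients),
# constructed from synthetic exact-line data.
exact_universal_models <- function() {
  x <- seq(1, 40, length.out = 12)
  list(pm2_5 = quiet(fit_calibration((x * 8 + 3.82) / 4.07, x * 8,
                                     "averaged", "pm2_5")),
       pm10 = quiet(fit_calibration((x * 150 + 81.5) / 44.3, x * 150,
                                    "averaged", "pm10")))
}

# Direct Monte-Carlo draw of exposure records from the stated lognormal
# model, bypassing log generation (for model-level simulations).
mc_records <- function(n_horses, m_dry, m_soaked, horse_sd, resid_sd,
                       metric = "pm2_5", window = "extended") {
  b <- rnorm(n_horses, 0, horse_sd)
  horses <- sprintf("H%02d", seq_len(n_horses))
  data.frame(
    horse_id = rep(horses, 2L),
    treatment = rep(c("dry", "soaked"), each = n_horses),
    metric = metric, window = window,
    mean_conc = exp(c(log(m_dry) + b + rnorm(n_horses, 0, resid_sd),
                      log(m_soaked) + b + rnorm(n_horses, 0, resid_sd))),
    n_samples = 5760L)
}
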