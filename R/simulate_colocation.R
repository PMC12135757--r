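#' Configuration for the co-location chamber simulator
#'
#' Describes a chamber run in which hay dust is held at a sequence of
#' quasi-steady plateau concentrations while a reference TEOM (slow,
#' lagged), a fast comparison monitor, and three wearable optical units
#' sample the same air. Defaults emulate the calibration experiment: ten
#' plateaus spanning roughly 3.5-163 ug/m^3 (PM2.5) and 10-2540 ug/m^3
#' (PM10), a 4-min reference lag, and per-unit sensitivities such that the
#' expected raw wearable reading is `(true - alpha) / beta` for the
#' published per-unit calibration coefficients (beta, alpha).
#'
#' The reference response model is a pure delay of `teom_lag_min` combined
#' with a symmetric (zero-phase) moving-average of width
#' `teom_smoothing_min`: the smoothing expresses the instrument's sluggish
#' response without adding phase delay, so the configured delay is exactly
#' the net lag recoverable by cross-correlation.
#'
#' @param plateau_levels Named list of true plateau concentrations
#'   (ug/m^3), one numeric vector per size fraction (`pm2_5`, `pm10`); the
#'   two fractions run on the same clock (same chamber air).
#' @param plateau_duration_min Minutes per plateau (>= 5; default 10).
#' @param transition_duration_min Linear ramp minutes between plateaus
#'   (default 3).
#' @param teom_lag_min Integer reference-instrument delay in minutes
#'   (default 4).
#' @param teom_smoothing_min Width of the symmetric response-smoothing
#'   window in minutes (default 2; 0 disables smoothing).
#' @param unit_params Named list (per fraction) of data frames with columns
#'   `unit_id`, `beta`, `alpha`: expected raw reading = (true - alpha)/beta.
#' @param noise_cv Multiplicative lognormal noise CV of a wearable 5-s
#'   sample (default 0.05).
#' @param teom_noise_cv,comparison_noise_cv Lognormal noise CV of a 1-min
#'   reference / comparison value (defaults 0.005).
#' @param start_time First sample timestamp.
#' @param seed Integer RNG seed.
#' @return An object of class `colocation_config`.
#' @export
colocation_config <- function(plateau_levels = list(
                                pm2_5 = c(5, 10, 20, 40, 60, 80, 100, 120, 140, 155),
                                pm10 = c(55, 125, 270, 560, 850, 1140, 1440, 1730, 2020, 2450)),
                              plateau_duration_min = 10,
                              transition_duration_min = 3,
                              teom_lag_min = 4,
                              teom_smoothing_min = 2,
                              unit_params = default_unit_params(),
                              noise_cv = 0.05,
                              teom_noise_cv = 0.005,
                              comparison_noise_cv = 0.005,
                              start_time = as.POSIXct("2023-03-01 08:00:00", tz = "UTC"),
                              seed = 1L) {
  cfg <- structure(
    list(plateau_levels = plateau_levels,
         plateau_duration_min = plateau_duration_min,
         transition_duration_min = transition_duration_min,
         teom_lag_min = teom_lag_min,
         teom_smoothing_min = teom_smoothing_min,
         unit_params = unit_params,
         noise_cv = noise_cv,
         teom_noise_cv = teom_noise_cv,
         comparison_noise_cv = comparison_noise_cv,
         start_time = start_time,
         seed = seed),
    class = "colocation_config")
  validate_colocation_config(cfg)
}

validate_colocation_config <- function(cfg) {
  if (!all(c("pm2_5", "pm10") %in% names(cfg$plateau_levels)))
    stop("plateau_levels must name pm2_5 and pm10", call. = FALSE)
  lens <- lengths(cfg$plateau_levels)
  if (length(unique(lens)) != 1L)
    stop("both fractions need the same number of plateau levels", call. = FALSE)
  if (any(unlist(cfg$plateau_levels) <= 0))
    stop("plateau levels must be positive", call. = FALSE)
  if (cfg$plateau_duration_min < 5)
    stop("plateau_duration_min must be >= 5 (steady intervals need 5 min)",
         call. = FALSE)
  if (cfg$teom_lag_min < 0 || cfg$teom_lag_min != round(cfg$teom_lag_min))
    stop("teom_lag_min must be a non-negative integer", call. = FALSE)
  for (frac in c("pm2_5", "pm10")) {
    up <- cfg$unit_params[[frac]]
    if (is.null(up) || !all(c("unit_id", "beta", "alpha") %in% names(up)))
      stop("unit_params$", frac, " must have unit_id, beta, alpha", call. = FALSE)
    if (any(up$beta <= 0)) stop("unit beta must be > 0", call. = FALSE)
  }
  if (any(c(cfg$noise_cv, cfg$teom_noise_cv, cfg$comparison_noise_cv) < 0))
    stop("noise CVs must be >= 0", call. = FALSE)
  cfg
}

# Published per-unit calibration coefficients (TEOM = beta * raw + alpha),
# used as generating truth for the simulated wearable units.
default_unit_params <- function() {
  list(
    pm2_5 = data.frame(unit_id = c("BB1", "BB2", "BB3"),
                       beta = c(4.48, 4.16, 3.60),
                       alpha = c(-5.17, -2.82, -2.58)),
    pm10 = data.frame(unit_id = c("BB1", "BB2", "BB3"),
                      beta = c(45.8, 44.6, 42.0),
                      alpha = c(-113.7, -51.6, -65.3)))
}

# Internal: piecewise plateau + linear ramp truth path on a 5-s grid.
plateau_truth <- function(levels, dur_min, trans_min, n_samples) {
  xs <- numeric(0); ys <- numeric(0); t <- 0
  for (L in levels) {
    xs <- c(xs, t, t + dur_min * 60)
    ys <- c(ys, L, L)
    t <- t + dur_min * 60 + trans_min * 60
  }
  tt <- (seq_len(n_samples) - 1L) * 5
  approx(xs, ys, xout = tt, rule = 2)$y
}

# Internal: symmetric moving average (zero phase), edge-padded.
smooth_symmetric <- function(x, width_samples) {
  if (width_samples <= 1) return(x)
  h <- floor(width_samples / 2)
  k <- 2L * h + 1L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(h + 1):(h + length(x))]
}

lognorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

# Internal: assemble a full wearable record frame from raw mass channels.
# Number bins are derived deterministically from the mass channels with the
# cumulative ordering enforced; temperature/RH are held at chamber-typical
# constants; GPS is absent (indoor).
wearable_records <- function(timestamp, raw25, raw10) {
  n <- length(timestamp)
  if (is.null(raw25)) raw25 <- 0.5 * raw10
  if (is.null(raw10)) raw10 <- 2 * raw25
  raw10 <- pmax(raw10, raw25)          # cumulative mass: pm10 >= pm2_5
  pm1 <- 0.5 * raw25
  n03 <- round(250 * raw25)
  n05 <- pmin(n03, round(70 * raw25))
  n1 <- pmin(n05, round(12 * raw25))
  n25 <- pmin(n1, round(1.5 * raw10))
  n5 <- pmin(n25, round(0.3 * raw10))
  n10 <- pmin(n5, round(0.05 * raw10))
  data.frame(timestamp = timestamp, pm1 = pm1, pm2_5 = raw25, pm10 = raw10,
             n_gt_0_3 = n03, n_gt_0_5 = n05, n_gt_1_0 = n1,
             n_gt_2_5 = n25, n_gt_5_0 = n5, n_gt_10 = n10,
             temp_c = rep_len(22.4, n), rh_pct = rep_len(18.0, n),
             lat = rep_len(NA_real_, n), lon = rep_len(NA_real_, n))
}

#' Simulate a co-location chamber run
#'
#' Generates, from a [colocation_config()], the full instrument ensemble of
#' a calibration experiment: two reference series (one per size fraction,
#' 1-min cadence, delayed and smoothed, multiplicative noise), two
#' comparison series (1-min means of the truth, zero lag, small noise), and
#' three wearable units logging raw 5-s readings
#' `max(0, (true - alpha_i)/beta_i) * exp(eps)` with lognormal noise.
#' Output is reproducible from `config$seed`.
#'
#' @param config A [colocation_config()].
#' @return A list of class `pm_colocation_sim` with elements `teom` and
#'   `comparison` (each a list with `pm2_5` and `pm10` [pm_series()]),
#'   `wearables` (list of three wearable [pm_series()]), `truth` (5-s truth
#'   paths and the plateau schedule), and `config`.
#' @export
simulate_colocation <- function(config) {
  stopifnot(inherits(config, "colocation_config"))
  validate_colocation_config(config)
  n_p <- length(config$plateau_levels$pm2_5)
  total_min <- n_p * config$plateau_duration_min +
    (n_p - 1) * config$transition_duration_min
  n5 <- total_min * 12L
  times <- config$start_time + (seq_len(n5) - 1L) * 5
  truth <- lapply(config$plateau_levels, plateau_truth,
                  dur_min = config$plateau_duration_min,
                  trans_min = config$transition_duration_min,
                  n_samples = n5)
  minute_start <- config$start_time + (seq_len(total_min) - 1L) * 60
  min_means <- function(x) rowMeans(matrix(x, ncol = 12L, byrow = TRUE))
  lag_samples <- config$teom_lag_min * 12L
  delay <- function(x) {
    if (lag_samples == 0) x
    else c(rep(x[1], lag_samples), x[seq_len(n5 - lag_samples)])
  }
  with_seed(config$seed, {
    teom <- list(); comparison <- list()
    for (frac in c("pm2_5", "pm10")) {
      sm <- smooth_symmetric(truth[[frac]],
                             config$teom_smoothing_min * 12L + 1L)
      tv <- min_means(delay(sm)) *
        exp(rnorm(total_min, 0, lognorm_sdlog(config$teom_noise_cv)))
      cv <- min_means(truth[[frac]]) *
        exp(rnorm(total_min, 0, lognorm_sdlog(config$comparison_noise_cv)))
      lab <- if (frac == "pm2_5") "pm2_5" else "pm10"
      teom[[frac]] <- pm_series(paste0("TEOM-", toupper(gsub("_", ".", lab))),
                                "teom", lab,
                                data.frame(timestamp = minute_start, value = tv))
      comparison[[frac]] <- pm_series(paste0("DY-", toupper(gsub("_", ".", lab))),
                                      "comparison", lab,
                                      data.frame(timestamp = minute_start, value = cv))
    }
    sdlog <- lognorm_sdlog(config$noise_cv)
    wearables <- lapply(seq_len(nrow(config$unit_params$pm2_5)), function(i) {
      p25 <- config$unit_params$pm2_5[i, ]
      p10 <- config$unit_params$pm10[i, ]
      raw25 <- pmax(0, (truth$pm2_5 - p25$alpha) / p25$beta) *
        exp(rnorm(n5, 0, sdlog))
      raw10 <- pmax(0, (truth$pm10 - p10$alpha) / p10$beta) *
        exp(rnorm(n5, 0, sdlog))
      pm_series(p25$unit_id, "wearable", "both",
                wearable_records(times, raw25, raw10))
    })
    names(wearables) <- config$unit_params$pm2_5$unit_id
    structure(
      list(teom = teom, comparison = comparison, wearables = wearables,
           truth = list(time = times, pm2_5 = truth$pm2_5, pm10 = truth$pm10,
                        schedule = plateau_schedule(config)),
           config = config),
      class = "pm_colocation_sim")
  })
}

# Internal: plateau start/end instants for truth-based test oracles.
plateau_schedule <- function(config) {
  n_p <- length(config$plateau_levels$pm2_5)
  step <- (config$plateau_duration_min + config$transition_duration_min) * 60
  start <- config$start_time + (seq_len(n_p) - 1L) * step
  data.frame(plateau = seq_len(n_p),
             start = start,
             end = start + config$plateau_duration_min * 60,
             level_pm2_5 = config$plateau_levels$pm2_5,
             level_pm10 = config$plateau_levels$pm10)
}

#' @export
print.pm_colocation_sim <- function(x, ...) {
  cat(sprintf("<pm_colocation_sim> %d plateaus, %d wearable units, seed %d\n",
              nrow(x$truth$schedule), length(x$wearables),
              as.integer(x$config$seed)))
  invisible(x)
}
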