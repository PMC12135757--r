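#' Calibrated window exposure from a raw log
#'
#' Computes the average breathing-zone exposure over one analysis window:
#' the arithmetic mean of the raw 5-s samples in
#' `[feed_time, feed_time + 20 min)` (short) or
#' `[feed_time, feed_time + 8 h)` (extended), corrected through the
#' calibration (the correction is affine, so correcting the window mean
#' equals averaging corrected samples) and floored at 0 at this reporting
#' stage. The window must hold at least 75% of its expected samples.
#'
#' @param series Raw wearable [pm_series()].
#' @param model [fit_calibration()] model for the channel being corrected.
#' @param feed_time Instant the forage was offered (`POSIXct`).
#' @param window `"short"` (20 min) or `"extended"` (8 h).
#' @return One-row data frame: `metric`, `window`, `mean_conc` (ug/m^3),
#'   `n_samples`.
#' @export
window_exposure <- function(series, model, feed_time,
                            window = c("short", "extended")) {
  window <- match.arg(window)
  len_s <- if (window == "short") 20 * 60 else 8 * 3600
  channel <- model$size_fraction
  v <- window_samples(series, channel, feed_time, feed_time + len_s)
  expected <- len_s / series$cadence_s
  if (length(v) < 0.75 * expected)
    stop(sprintf(
      "insufficient coverage of the %s window starting %s: %d of %d expected samples",
      window, fmt_ts(feed_time), length(v), as.integer(expected)), call. = FALSE)
  corrected <- max(0, model$slope * mean(v) + model$intercept)
  data.frame(metric = channel, window = window,
             mean_conc = corrected, n_samples = length(v))
}

#' Exposure table for a whole trial
#'
#' Applies [window_exposure()] to every horse-day log of a simulated (or
#' assembled) trial for both metrics and both windows.
#'
#' @param sim A `pm_trial_sim` (or any list with `logs` and `metadata` in
#'   the same layout).
#' @param models Named list of calibration models, one per metric
#'   (`pm2_5`, `pm10`).
#' @return Data frame of exposure records: `horse_id`, `treatment`,
#'   `metric`, `window`, `mean_conc`, `n_samples`.
#' @export
trial_exposures <- function(sim, models) {
  md <- sim$metadata
  rows <- list()
  for (i in seq_len(nrow(md))) {
    log <- sim$logs[[md$log_id[i]]]
    if (is.null(log)) stop("missing log: ", md$log_id[i], call. = FALSE)
    for (metric in names(models)) {
      for (win in c("short", "extended")) {
        r <- window_exposure(log, models[[metric]], md$feed_time[i], win)
        r$horse_id <- md$horse_id[i]
        r$treatment <- md$treatment[i]
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  out <- do.call(rbind, rows)
  out[, c("horse_id", "treatment", "metric", "window", "mean_conc", "n_samples")]
}

# Internal: shared record preparation for the mixed models. Replaces zero
# window means (possible after reporting-stage flooring) by 0.1 ug/m^3
# before logging, drops horses without both treatments.
prepare_trial_records <- function(records) {
  zero <- records$mean_conc <= 0
  if (any(zero)) {
    message(sum(zero), " zero window mean(s) replaced by 0.1 ug/m^3 before ",
            "log-transform")
    records$mean_conc[zero] <- 0.1
  }
  tab <- table(records$horse_id, records$treatment)
  paired <- rownames(tab)[rowSums(tab > 0) == 2]
  unpaired <- setdiff(unique(records$horse_id), paired)
  if (length(unpaired)) {
    warning("excluding unpaired horse(s): ", paste(unpaired, collapse = ", "),
            call. = FALSE)
    records <- records[records$horse_id %in% paired, , drop = FALSE]
  }
  if (length(paired) < 3) stop("need >= 3 paired horses", call. = FALSE)
  records$treatment <- factor(records$treatment, c("dry", "soaked"))
  records$horse_id <- factor(records$horse_id)
  records$log_conc <- log(records$mean_conc)
  records
}

back_transform_emm <- function(emm) {
  es <- as.data.frame(emm)
  cells <- es[, setdiff(names(es), c("emmean", "SE", "df", "lower.CL",
                                     "upper.CL")), drop = FALSE]
  cbind(cells,
        data.frame(lsmean = exp(es$emmean),
                   lower = exp(es$lower.CL),
                   upper = exp(es$upper.CL),
                   df = es$df))
}

varcomp_of <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  c(sd_horse = vc$sdcor[vc$grp == "horse_id"][1],
    sd_resid = vc$sdcor[vc$grp == "Residual"][1])
}

#' Treatment effect on window exposure (lognormal repeated measures)
#'
#' Fits the cross-over treatment model for one metric and one window: a
#' linear mixed model on the natural log of the window mean with a fixed
#' hay-treatment effect and a random horse intercept (the
#' repeated-measures structure; for two occasions this coincides with a
#' compound-symmetry repeated-measures formulation). Estimation is REML
#' with Satterthwaite denominator degrees of freedom; least-squares means
#' and their 95% confidence limits are back-transformed by exponentiation.
#'
#' @param records Exposure records (one metric, one window), as produced
#'   by [trial_exposures()].
#' @param conf_level Confidence level for the least-squares means
#'   (default 0.95).
#' @return An object of class `pm_trial_fit`: back-transformed `lsmeans`,
#'   `effects` (p-values), Tukey-adjusted `contrasts` where more than one
#'   pairwise comparison exists (a single 2-level comparison reduces to the
#'   unadjusted test), log-scale variance components, and the underlying
#'   fit.
#' @export
fit_treatment_model <- function(records, conf_level = 0.95) {
  metric <- unique(records$metric)
  win <- unique(records$window)
  if (length(metric) != 1L || length(win) != 1L)
    stop("records must cover exactly one metric and one window", call. = FALSE)
  d <- prepare_trial_records(records)
  fit <- lmerTest::lmer(log_conc ~ treatment + (1 | horse_id), data = d,
                        REML = TRUE)
  aov <- anova(fit)  # Satterthwaite type III
  emm <- emmeans::emmeans(fit, ~treatment, lmer.df = "satterthwaite",
                          level = conf_level)
  structure(
    list(metric = metric, window = win,
         model_kind = "treatment_only_per_window",
         lsmeans = back_transform_emm(emm),
         effects = c(treatment = aov["treatment", "Pr(>F)"]),
         contrasts = as.data.frame(emmeans::contrast(emm, "pairwise")),
         varcomp = varcomp_of(fit),
         conf_level = conf_level,
         n_horses = nlevels(d$horse_id),
         records = d,
         fit = fit),
    class = "pm_trial_fit")
}

#' Treatment x measurement-duration model
#'
#' Fits, for one metric, the model comparing the short (20-min) and
#' extended (8-h) windows: fixed effects for hay treatment, measurement
#' duration, and their interaction, with a random horse intercept, on the
#' log scale. Pairwise comparisons among the four treatment-by-duration
#' cells are Tukey-adjusted; treatment-marginal least-squares means
#' (averaged over windows) are also reported so the soaked-vs-dry
#' reduction is available from this fit.
#'
#' @param records Exposure records for one metric, both windows.
#' @inheritParams fit_treatment_model
#' @return A `pm_trial_fit` with `model_kind = "treatment_x_duration"`,
#'   cell `lsmeans`, `effects` p-values for treatment, duration and
#'   interaction, and Tukey-adjusted `contrasts`.
#' @export
fit_duration_model <- function(records, conf_level = 0.95) {
  metric <- unique(records$metric)
  if (length(metric) != 1L)
    stop("records must cover exactly one metric", call. = FALSE)
  if (!all(c("short", "extended") %in% records$window))
    stop("records must contain both windows", call. = FALSE)
  d <- prepare_trial_records(records)
  d$window <- factor(d$window, c("short", "extended"))
  fit <- lmerTest::lmer(log_conc ~ treatment * window + (1 | horse_id),
                        data = d, REML = TRUE)
  aov <- anova(fit)
  emm <- emmeans::emmeans(fit, ~ treatment * window,
                          lmer.df = "satterthwaite", level = conf_level)
  emm_trt <- suppressMessages(
    emmeans::emmeans(fit, ~treatment, lmer.df = "satterthwaite",
                     level = conf_level))
  structure(
    list(metric = metric, window = "both",
         model_kind = "treatment_x_duration",
         lsmeans = back_transform_emm(emm),
         treatment_lsmeans = back_transform_emm(emm_trt),
         effects = c(treatment = aov["treatment", "Pr(>F)"],
                     duration = aov["window", "Pr(>F)"],
                     interaction = aov["treatment:window", "Pr(>F)"]),
         contrasts = as.data.frame(
           emmeans::contrast(emm, "pairwise", adjust = "tukey")),
         varcomp = varcomp_of(fit),
         conf_level = conf_level,
         n_horses = nlevels(d$horse_id),
         records = d,
         fit = fit),
    class = "pm_trial_fit")
}

#' Percent exposure reduction, soaked vs dry
#'
#' `100 * (1 - lsmean_soaked / lsmean_dry)` from a fitted trial model
#' (treatment-marginal least-squares means for the duration model).
#'
#' @param result A `pm_trial_fit`.
#' @return Percent reduction.
#' @export
percent_reduction <- function(result) {
  stopifnot(inherits(result, "pm_trial_fit"))
  ls <- if (result$model_kind == "treatment_x_duration")
    result$treatment_lsmeans else result$lsmeans
  dry <- ls$lsmean[ls$treatment == "dry"]
  soaked <- ls$lsmean[ls$treatment == "soaked"]
  100 * (1 - soaked / dry)
}

#' @export
print.pm_trial_fit <- function(x, ...) {
  frac <- toupper(gsub("_", ".", x$metric))
  if (x$model_kind == "treatment_only_per_window") {
    cat(sprintf("%s %s-window exposure model (%d horses, cross-over)\n",
                frac, x$window, x$n_horses))
  } else {
    cat(sprintf("%s treatment x duration exposure model (%d horses)\n",
                frac, x$n_horses))
  }
  ls <- x$lsmeans
  lab <- if ("window" %in% names(ls))
    paste(ls$treatment, ls$window, sep = "/") else as.character(ls$treatment)
  cat(sprintf("  lsmeans (back-transformed, %d%% CI):\n",
              round(100 * x$conf_level)))
  for (i in seq_len(nrow(ls)))
    cat(sprintf("    %-16s %8.1f  [%.1f, %.1f] ug/m^3\n",
                lab[i], ls$lsmean[i], ls$lower[i], ls$upper[i]))
  cat("  p-values:",
      paste(sprintf("%s = %.4g", names(x$effects), x$effects), collapse = ", "),
      "\n")
  cat(sprintf("  log-scale SDs: horse %.3f, residual %.3f\n",
              x$varcomp[["sd_horse"]], x$varcomp[["sd_resid"]]))
  if (x$model_kind != "treatment_x_duration")
    cat(sprintf("  soaked vs dry reduction: %.1f%%\n", percent_reduction(x)))
  invisible(x)
}

#' @export
summary.pm_trial_fit <- function(object, ...) {
  print(object)
  cat("  pairwise contrasts",
      if (nrow(object$contrasts) > 1) "(Tukey-adjusted)" else "(unadjusted)",
      ":\n")
  print(object$contrasts, row.names = FALSE, digits = 3)
  invisible(object)
}

#' Plot least-squares means with observations
#'
#' Reproduces the trial's summary figure style: back-transformed
#' least-squares means (solid points) with confidence-interval whiskers,
#' overlaid on the individual horse-day window means (open circles), on
#' the original concentration scale.
#'
#' @param x A `pm_trial_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.pm_trial_fit <- function(x, ...) {
  ls <- x$lsmeans
  lab <- if ("window" %in% names(ls))
    paste(ls$treatment, ls$window, sep = "\n") else as.character(ls$treatment)
  k <- nrow(ls)
  obs <- x$records
  grp <- if ("window" %in% names(ls))
    match(paste(obs$treatment, obs$window), paste(ls$treatment, ls$window))
  else match(obs$treatment, ls$treatment)
  ylim <- range(0, ls$upper, obs$mean_conc)
  plot(NA, xlim = c(0.5, k + 0.5), ylim = ylim, xaxt = "n",
       xlab = "", ylab = sprintf("%s (ug/m^3)", toupper(gsub("_", ".", x$metric))),
       ...)
  axis(1, at = seq_len(k), labels = lab, padj = 0.5)
  points(jitter(grp, amount = 0.08), obs$mean_conc, col = "grey50")
  arrows(seq_len(k), ls$lower, seq_len(k), ls$upper,
         angle = 90, code = 3, length = 0.06)
  points(seq_len(k), ls$lsmean, pch = 19, cex = 1.3)
  invisible(x)
}
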