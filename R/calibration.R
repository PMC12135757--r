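#' Fit a linear calibration against reference means
#'
#' Ordinary least squares of the reference (TEOM) interval means on the
#' raw monitor interval means, with the reference as the dependent
#' variable: `corrected = beta * raw + alpha`. Reported diagnostics follow
#' sensor-calibration convention: coefficient of determination r^2, RMSE as
#' the residual root-mean-square `sqrt(SSE / n)` (population form, recorded
#' as `rmse_convention = "sse_over_n"` on serialisation), two-sided slope
#' p-value from the t distribution, and a Shapiro-Wilk test of residual
#' normality.
#'
#' @param x Raw monitor interval means (predictor).
#' @param y Reference interval means (response), same length.
#' @param unit_id Label for the unit being calibrated (or `"averaged"`).
#' @param size_fraction `"pm2_5"` or `"pm10"`.
#' @return An object of class `pm_calibration` with components `slope`,
#'   `intercept`, `r2`, `rmse`, `n_obs`, `p_slope`, `shapiro_w`,
#'   `shapiro_p`, plus the underlying `lm` fit and data.
#' @seealso [fit_universal()], [apply_calibration()], [predict.pm_calibration()]
#' @export
fit_calibration <- function(x, y, unit_id = "unit", size_fraction = "pm2_5") {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n)
    stop("need at least 3 paired observations", call. = FALSE)
  if (sd(x) == 0)
    stop("predictor is constant: slope unidentifiable", call. = FALSE)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  res <- residuals(fit)
  sw <- if (n >= 3 && n <= 5000) shapiro.test(res) else list(statistic = NA_real_, p.value = NA_real_)
  structure(
    list(unit_id = unit_id,
         size_fraction = size_fraction,
         slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r2 = sm$r.squared,
         rmse = sqrt(mean(res^2)),
         n_obs = n,
         p_slope = sm$coefficients[2, 4],
         shapiro_w = unname(sw$statistic),
         shapiro_p = sw$p.value,
         fit = fit,
         data = data.frame(raw = x, reference = y)),
    class = "pm_calibration")
}

#' Shapiro-Wilk test of residual normality
#'
#' Thin wrapper around [stats::shapiro.test()] with the calibration
#' module's domain checks (3 <= n <= 5000).
#'
#' @param residuals Numeric residual vector.
#' @return Named numeric `c(w, p)`.
#' @export
shapiro_wilk <- function(residuals) {
  n <- length(residuals)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  sw <- shapiro.test(residuals)
  c(w = unname(sw$statistic), p = sw$p.value)
}

#' Fit per-unit calibrations from matched intervals
#'
#' @param matched Matched-interval table from [build_matched_intervals()].
#' @param size_fraction Recorded on each model (`"pm2_5"` or `"pm10"`).
#' @return Named list of [fit_calibration()] objects, one per unit.
#' @export
fit_unit_calibrations <- function(matched, size_fraction = attr(matched, "channel")) {
  units <- attr(matched, "units")
  out <- lapply(units, function(u)
    fit_calibration(matched[[u]], matched$teom_mean, u, size_fraction))
  names(out) <- units
  out
}

#' Fit the universal (averaged-unit) calibration
#'
#' Averages the per-interval means of all units into a single predictor and
#' regresses the reference means on it — a fresh regression on the
#' across-unit mean, not an average of per-unit coefficients. The resulting
#' formula applies to any unit of the monitor family. Intervals missing any
#' unit are excluded with a message.
#'
#' @inheritParams fit_unit_calibrations
#' @return A [fit_calibration()] object with `unit_id = "averaged"`.
#' @export
fit_universal <- function(matched, size_fraction = attr(matched, "channel")) {
  units <- attr(matched, "units")
  m <- as.matrix(matched[, units, drop = FALSE])
  keep <- stats::complete.cases(m)
  if (any(!keep))
    message(sum(!keep), " interval(s) excluded from the universal fit: ",
            "missing unit mean")
  if (sum(keep) < 3)
    stop("need >= 3 intervals with all units present", call. = FALSE)
  fit_calibration(rowMeans(m[keep, , drop = FALSE]),
                  matched$teom_mean[keep], "averaged", size_fraction)
}

#' Apply a calibration to a raw series
#'
#' Corrects every raw value by the affine formula
#' `corrected = slope * raw + intercept`. Individual corrected samples are
#' deliberately NOT floored at zero: the correction is affine, so window
#' means may be corrected directly, and flooring is applied only at the
#' reporting (window-mean) stage to preserve regression-scale linearity.
#'
#' @param model A [fit_calibration()] object.
#' @param series A [pm_series()].
#' @param channel Channel to correct; defaults to the model's
#'   `size_fraction` for wearables and `"value"` otherwise.
#' @return The series with the channel corrected (validation is bypassed:
#'   corrected values may legitimately be negative before window flooring).
#' @export
apply_calibration <- function(model, series, channel = NULL) {
  stopifnot(inherits(model, "pm_calibration"), inherits(series, "pm_series"))
  if (is.null(channel))
    channel <- if (series$instrument_kind == "wearable") model$size_fraction else "value"
  if (!channel %in% names(series$data))
    stop("channel '", channel, "' not present in series", call. = FALSE)
  series$data[[channel]] <- model$slope * series$data[[channel]] + model$intercept
  series$calibrated <- TRUE
  series
}

#' @export
print.pm_calibration <- function(x, digits = 3, ...) {
  frac <- toupper(gsub("_", ".", x$size_fraction))
  cat(sprintf("%s calibration - unit %s (n = %d)\n", frac, x$unit_id, x$n_obs))
  cat(sprintf("  reference = %.*g x raw %s %.*g\n", digits + 1, x$slope,
              ifelse(x$intercept < 0, "-", "+"), digits + 1, abs(x$intercept)))
  cat(sprintf("  r^2 = %.3f, RMSE = %.3g ug/m^3, slope p = %.2g\n",
              x$r2, x$rmse, x$p_slope))
  invisible(x)
}

#' @export
summary.pm_calibration <- function(object, ...) {
  print(object)
  cat(sprintf("  Shapiro-Wilk residual normality: W = %.3f, p = %.3g\n",
              object$shapiro_w, object$shapiro_p))
  cat("  RMSE convention: sqrt(SSE/n)\n")
  invisible(object)
}

#' @export
coef.pm_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict corrected concentrations from raw readings
#'
#' @param object A [fit_calibration()] object.
#' @param raw Numeric vector of raw readings; defaults to the training data.
#' @param ... Unused.
#' @return Corrected concentrations `slope * raw + intercept` (ug/m^3).
#' @export
predict.pm_calibration <- function(object, raw = NULL, ...) {
  if (is.null(raw)) raw <- object$data$raw
  object$slope * raw + object$intercept
}

#' @export
residuals.pm_calibration <- function(object, ...) residuals(object$fit)

#' @export
plot.pm_calibration <- function(x, ...) {
  frac <- toupper(gsub("_", ".", x$size_fraction))
  plot(x$data$raw, x$data$reference,
       xlab = sprintf("raw %s (%s)", frac, x$unit_id),
       ylab = sprintf("reference %s (ug/m^3)", frac),
       main = sprintf("%s = %.3g x raw %+.3g  (r^2 = %.3f)",
                      frac, x$slope, x$intercept, x$r2), ...)
  abline(x$intercept, x$slope, col = "red3")
  invisible(x)
}

#' Serialise a calibration model to JSON
#'
#' @param model A [fit_calibration()] object.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
calibration_to_json <- function(model, path) {
  jsonlite::write_json(
    list(size_fraction = model$size_fraction, unit_id = model$unit_id,
         slope = model$slope, intercept = model$intercept, r2 = model$r2,
         rmse_ug_m3 = model$rmse, n_obs = model$n_obs,
         p_slope = model$p_slope, shapiro_w = model$shapiro_w,
         shapiro_p = model$shapiro_p, rmse_convention = "sse_over_n"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a calibration model from JSON
#'
#' Restores the coefficients and diagnostics written by
#' [calibration_to_json()]; the underlying `lm` fit is not persisted, so
#' the restored object supports prediction and application but not
#' residual extraction.
#'
#' @param path JSON file written by [calibration_to_json()].
#' @return A `pm_calibration` object.
#' @export
calibration_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(unit_id = j$unit_id, size_fraction = j$size_fraction,
         slope = j$slope, intercept = j$intercept, r2 = j$r2,
         rmse = j$rmse_ug_m3, n_obs = j$n_obs, p_slope = j$p_slope,
         shapiro_w = j$shapiro_w, shapiro_p = j$shapiro_p,
         fit = NULL, data = NULL),
    class = "pm_calibration")
}

#' Pooled inter-unit coefficient of variation
#'
#' Precision statistic across co-located units: for each matched interval
#' the CV of the per-unit means (sample SD over mean) is computed, and the
#' per-interval CVs are pooled by root-mean-square,
#' `100 * sqrt(mean(cv_j^2))` percent. Intervals whose cross-unit mean is
#' not positive are excluded with a message.
#'
#' @param matched Matched-interval table from [build_matched_intervals()].
#' @return Pooled CV in percent.
#' @export
interunit_cv <- function(matched) {
  units <- attr(matched, "units")
  if (length(units) < 2) stop("need >= 2 units", call. = FALSE)
  m <- as.matrix(matched[, units, drop = FALSE])
  if (nrow(m) < 2) stop("need >= 2 intervals", call. = FALSE)
  mu <- rowMeans(m)
  bad <- mu <= 0
  if (any(bad)) {
    message(sum(bad), " interval(s) excluded from CV: cross-unit mean <= 0")
    m <- m[!bad, , drop = FALSE]
    mu <- mu[!bad]
  }
  cvs <- apply(m, 1, sd) / mu
  100 * sqrt(mean(cvs^2))
}

#' Pairwise Pearson correlations between units
#'
#' @param matched Matched-interval table from [build_matched_intervals()]
#'   with at least 3 intervals.
#' @return Symmetric correlation matrix over unit interval means; a
#'   constant unit yields `NA` entries (undefined correlation).
#' @export
pairwise_correlations <- function(matched) {
  units <- attr(matched, "units")
  m <- as.matrix(matched[, units, drop = FALSE])
  if (nrow(m) < 3) stop("need >= 3 intervals", call. = FALSE)
  r <- suppressWarnings(cor(m))
  diag(r) <- 1
  r
}

#' Inter-unit precision report
#'
#' Bundles the pooled CV and the pairwise correlation matrix for one size
#' fraction.
#'
#' @inheritParams interunit_cv
#' @param size_fraction Label recorded on the report.
#' @return Object of class `pm_precision` with `cv_percent`, `pairwise_r`,
#'   `n_intervals`, `size_fraction`.
#' @export
precision_report <- function(matched, size_fraction = attr(matched, "channel")) {
  structure(
    list(size_fraction = size_fraction,
         cv_percent = interunit_cv(matched),
         pairwise_r = pairwise_correlations(matched),
         n_intervals = nrow(matched)),
    class = "pm_precision")
}

#' @export
print.pm_precision <- function(x, ...) {
  cat(sprintf("%s inter-unit precision over %d matched intervals\n",
              toupper(gsub("_", ".", x$size_fraction)), x$n_intervals))
  cat(sprintf("  pooled CV: %.2f%%\n", x$cv_percent))
  off <- x$pairwise_r[upper.tri(x$pairwise_r)]
  cat(sprintf("  pairwise Pearson r: min %.4f, max %.4f\n",
              min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  invisible(x)
}
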