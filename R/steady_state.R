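#' Rolling coefficient of variation over minute means
#'
#' Computes the sample coefficient of variation (SD/mean, n-1 denominator)
#' over every window of `window_min` consecutive complete minutes. Gaps in
#' the minute grid and incomplete minutes split windows; windows whose mean
#' is not positive are skipped (CV undefined).
#'
#' @param minutes A minute-mean data frame from [resample_to_minutes()].
#' @param window_min Window length in minutes (>= 2; default 5).
#' @return Data frame with columns `window_start` and `cv`; empty when
#'   fewer complete minutes than `window_min` are available.
#' @export
rolling_cv <- function(minutes, window_min = 5) {
  if (window_min < 2) stop("window_min must be >= 2", call. = FALSE)
  out <- list()
  for (blk in contiguous_blocks(minutes)) {
    n <- nrow(blk)
    if (n < window_min) next
    for (i in seq_len(n - window_min + 1L)) {
      v <- blk$value[i:(i + window_min - 1L)]
      m <- mean(v)
      if (m <= 0) next
      out[[length(out) + 1L]] <- data.frame(window_start = blk$minute_start[i],
                                            cv = sd(v) / m)
    }
  }
  if (!length(out))
    return(data.frame(window_start = as.POSIXct(character(), tz = "UTC"),
                      cv = numeric()))
  do.call(rbind, out)
}

# Internal: split a minute table into runs of consecutive complete minutes.
contiguous_blocks <- function(minutes) {
  m <- minutes[minutes$complete, , drop = FALSE]
  if (!nrow(m)) return(list())
  brk <- c(TRUE, diff(as.numeric(m$minute_start)) != 60)
  split(m, cumsum(brk))
}

#' Detect quasi-steady-state intervals
#'
#' Screens 1-min averaged reference data for quasi-steady-state operation:
#' a minute run qualifies when every `min_duration_min`-minute window
#' within it has a coefficient of variation below `cv_threshold` (the
#' screening rule is CV < 1% over at least 5 min). Each maximal qualifying
#' run is then reduced to consecutive non-overlapping 5-min reporting
#' intervals taken from the run's start, so the regression never sees
#' overlapping (pseudo-replicated) observations.
#'
#' @param minutes A minute-mean data frame from [resample_to_minutes()].
#' @param cv_threshold CV threshold (default 0.01).
#' @param min_duration_min Minimum steady duration and reporting-interval
#'   length in minutes (default 5).
#' @return Data frame of segments: `start`, `end`, `duration_min`,
#'   `teom_mean`, `cv`. Zero rows when nothing qualifies.
#' @export
detect_steady_segments <- function(minutes, cv_threshold = 0.01,
                                   min_duration_min = 5) {
  w <- as.integer(min_duration_min)
  segs <- list()
  for (blk in contiguous_blocks(minutes)) {
    n <- nrow(blk)
    if (n < w) next
    nwin <- n - w + 1L
    pass <- logical(nwin)
    for (i in seq_len(nwin)) {
      v <- blk$value[i:(i + w - 1L)]
      m <- mean(v)
      pass[i] <- m > 0 && sd(v) / m < cv_threshold
    }
    r <- rle(pass)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      # k consecutive passing windows starting at `starts[j]` cover
      # k + w - 1 minutes.
      cover <- r$lengths[j] + w - 1L
      n_int <- cover %/% w
      for (q in seq_len(n_int)) {
        i0 <- starts[j] + (q - 1L) * w
        v <- blk$value[i0:(i0 + w - 1L)]
        segs[[length(segs) + 1L]] <- data.frame(
          start = blk$minute_start[i0],
          end = blk$minute_start[i0] + w * 60,
          duration_min = w,
          teom_mean = mean(v),
          cv = sd(v) / mean(v))
      }
    }
  }
  if (!length(segs))
    return(data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_min = integer(), teom_mean = numeric(),
                      cv = numeric()))
  do.call(rbind, segs)
}

#' Estimate the reference instrument's response lag
#'
#' Cross-correlates the fast comparison series with the slow reference
#' series over integer minute lags `k = 0 ... max_lag_min`, pairing
#' `comparison(t)` with `reference(t + k)`, and reports the lag maximising
#' the Pearson correlation (ties broken toward the smaller lag). The sign
#' convention throughout the package: the reference LAGS the fast
#' instruments by `lag_min` minutes.
#'
#' @param reference,comparison Minute-mean data frames from
#'   [resample_to_minutes()] for the reference and comparison instruments.
#' @param max_lag_min Largest candidate lag in minutes (default 15).
#' @return An object of class `pm_lag`: list with `lag_min`,
#'   `peak_correlation`, and the full `correlations` table.
#' @export
estimate_lag <- function(reference, comparison, max_lag_min = 15) {
  ref <- reference[reference$complete, ]
  cmp <- comparison[comparison$complete, ]
  rk <- as.numeric(ref$minute_start) / 60
  ck <- as.numeric(cmp$minute_start) / 60
  lags <- 0:max_lag_min
  r <- numeric(length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    idx <- match(ck + k, rk)
    ok <- !is.na(idx)
    if (sum(ok) < 30)
      stop("insufficient overlap at lag ", k, ": need >= 30 overlapping ",
           "minutes, have ", sum(ok), call. = FALSE)
    r[i] <- cor(cmp$value[ok], ref$value[idx[ok]])
  }
  best <- which.max(r)  # first maximum: ties resolve toward smaller lag
  structure(list(lag_min = lags[best],
                 peak_correlation = r[best],
                 correlations = data.frame(lag_min = lags, r = r)),
            class = "pm_lag")
}

#' @export
print.pm_lag <- function(x, ...) {
  cat(sprintf("Reference response lag: %d min (peak Pearson r = %.4f)\n",
              x$lag_min, x$peak_correlation))
  cat("Convention: the reference lags the fast instruments;",
      "alignment shifts fast-instrument windows earlier.\n")
  invisible(x)
}

#' Assemble lag-aligned per-interval instrument means
#'
#' For each steady reference interval `[a, b)`, computes the matched means
#' of every fast instrument over the lag-aligned window
#' `[a - lag, b - lag)` (the fast instruments lead the lagged reference).
#' Intervals in which any instrument holds fewer than 75% of its expected
#' samples are dropped with a message.
#'
#' @param segments Segment table from [detect_steady_segments()].
#' @param lag_min Integer lag from [estimate_lag()] (or a `pm_lag` object).
#' @param wearables List of wearable [pm_series()].
#' @param comparison Comparison [pm_series()] for the same size fraction,
#'   or `NULL` to omit the comparison column.
#' @param channel Wearable channel to average (`"pm2_5"` or `"pm10"`).
#' @return Data frame of matched intervals: segment columns plus
#'   `comparison_mean` and one column per wearable `unit_id`; attribute
#'   `units` holds the unit column names and `channel` the channel.
#' @export
build_matched_intervals <- function(segments, lag_min, wearables,
                                    comparison = NULL, channel = "pm2_5") {
  if (inherits(lag_min, "pm_lag")) lag_min <- lag_min$lag_min
  if (!nrow(segments)) stop("no steady segments supplied", call. = FALSE)
  units <- vapply(wearables, function(w) w$unit_id, "")
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(segments))) {
    a <- segments$start[i] - lag_min * 60
    b <- segments$end[i] - lag_min * 60
    row <- segments[i, , drop = FALSE]
    ok <- TRUE
    if (!is.null(comparison)) {
      v <- window_samples(comparison, "value", a, b)
      if (length(v) < 0.75 * as.numeric(b - a, units = "secs") / comparison$cadence_s)
        ok <- FALSE
      row$comparison_mean <- mean(v)
    }
    for (j in seq_along(wearables)) {
      w <- wearables[[j]]
      v <- window_samples(w, channel, a, b)
      if (length(v) < 0.75 * as.numeric(b - a, units = "secs") / w$cadence_s)
        ok <- FALSE
      row[[units[j]]] <- mean(v)
    }
    if (ok) rows[[length(rows) + 1L]] <- row else dropped <- dropped + 1L
  }
  if (dropped > 0L)
    message(dropped, " interval(s) dropped: an instrument was missing >25% ",
            "of expected samples in the lag-aligned window")
  if (!length(rows)) stop("no complete matched intervals", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "units") <- unname(units)
  attr(out, "channel") <- channel
  out
}

window_samples <- function(series, channel, from, to) {
  ts <- series$data$timestamp
  series$data[[channel]][ts >= from & ts < to]
}
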