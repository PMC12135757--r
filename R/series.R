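#' Instrument log time series
#'
#' `pm_series()` builds the package's universal carrier for one instrument's
#' time-stamped records: a wearable optical monitor logging every 5 s, a
#' slow-response reference instrument (TEOM) at 1-min cadence, or a
#' fast-response comparison monitor at 1-min cadence.
#'
#' Wearable records carry mass concentrations (`pm1`, `pm2_5`, `pm10`,
#' ug/m^3), six cumulative particle-number bins (`n_gt_0_3` ... `n_gt_10`,
#' particles per 0.1 L, non-increasing in the size threshold), temperature
#' (`temp_c`), relative humidity (`rh_pct`), and optional GPS coordinates
#' (`lat`, `lon`, absent indoors). Reference and comparison records carry a
#' single `value` column. Timestamps are timezone-naive local time,
#' represented internally as UTC `POSIXct`.
#'
#' Validation enforces: strictly increasing timestamps (out-of-order records
#' are sorted with a warning; duplicates are an error), non-negative
#' concentrations, `pm1 <= pm2_5 <= pm10`, non-increasing cumulative number
#' bins, and relative humidity in \[0, 100\].
#'
#' @param unit_id Label for the physical unit (e.g. `"BB1"`).
#' @param instrument_kind One of `"wearable"`, `"teom"`, `"comparison"`.
#' @param size_fraction `"pm2_5"`, `"pm10"`, or `"both"` (wearables report
#'   all fractions in one log).
#' @param data A data frame of records; columns as described above with a
#'   `POSIXct` `timestamp` column.
#' @param validate Run record validation (default `TRUE`).
#' @return An object of class `pm_series`.
#' @seealso [read_pm_log()], [write_pm_log()], [resample_to_minutes()]
#' @export
pm_series <- function(unit_id, instrument_kind = c("wearable", "teom", "comparison"),
                      size_fraction = c("both", "pm2_5", "pm10"),
                      data, validate = TRUE) {
  instrument_kind <- match.arg(instrument_kind)
  size_fraction <- match.arg(size_fraction)
  cols <- if (instrument_kind == "wearable") wearable_cols else c("timestamp", "value")
  if (!is.data.frame(data) || !all(cols %in% names(data)))
    stop("`data` must contain columns: ", paste(cols, collapse = ", "), call. = FALSE)
  data <- data[, cols, drop = FALSE]
  if (!inherits(data$timestamp, "POSIXct"))
    stop("`timestamp` must be POSIXct", call. = FALSE)
  if (nrow(data) > 1L) {
    dt <- diff(as.numeric(data$timestamp))
    if (any(dt == 0))
      stop("duplicate timestamps at rows: ",
           paste(head(which(dt == 0) + 1L, 5L), collapse = ", "), call. = FALSE)
    if (any(dt < 0)) {
      warning("out-of-order timestamps; records sorted", call. = FALSE)
      data <- data[order(data$timestamp), , drop = FALSE]
      rownames(data) <- NULL
    }
  }
  obj <- structure(
    list(unit_id = as.character(unit_id),
         instrument_kind = instrument_kind,
         size_fraction = size_fraction,
         cadence_s = if (instrument_kind == "wearable") 5 else 60,
         data = data),
    class = "pm_series")
  if (validate) validate_records(obj)
  obj
}

wearable_cols <- c("timestamp", "pm1", "pm2_5", "pm10",
                   "n_gt_0_3", "n_gt_0_5", "n_gt_1_0", "n_gt_2_5",
                   "n_gt_5_0", "n_gt_10", "temp_c", "rh_pct", "lat", "lon")

# Internal: record-level invariant checks; errors name the offending rows.
validate_records <- function(series) {
  d <- series$data
  bad_rows <- function(cond) which(cond & !is.na(cond))
  name_rows <- function(i) paste(head(i, 5L), collapse = ", ")
  if (series$instrument_kind == "wearable") {
    for (col in c("pm1", "pm2_5", "pm10")) {
      i <- bad_rows(d[[col]] < 0)
      if (length(i)) stop("negative ", col, " at record(s): ", name_rows(i), call. = FALSE)
    }
    i <- bad_rows(d$pm1 > d$pm2_5 | d$pm2_5 > d$pm10)
    if (length(i))
      stop("mass-fraction ordering pm1 <= pm2_5 <= pm10 violated at record(s): ",
           name_rows(i), call. = FALSE)
    bins <- c("n_gt_0_3", "n_gt_0_5", "n_gt_1_0", "n_gt_2_5", "n_gt_5_0", "n_gt_10")
    m <- as.matrix(d[, bins])
    if (any(m < 0, na.rm = TRUE)) stop("negative particle counts", call. = FALSE)
    dec <- m[, -1, drop = FALSE] > m[, -length(bins), drop = FALSE]
    i <- bad_rows(rowSums(dec, na.rm = TRUE) > 0)
    if (length(i))
      stop("cumulative number bins must be non-increasing in threshold; ",
           "violated at record(s): ", name_rows(i), call. = FALSE)
    i <- bad_rows(d$rh_pct < 0 | d$rh_pct > 100)
    if (length(i)) stop("rh_pct outside [0,100] at record(s): ", name_rows(i), call. = FALSE)
  } else {
    i <- bad_rows(d$value < 0)
    if (length(i)) stop("negative value at record(s): ", name_rows(i), call. = FALSE)
  }
  invisible(series)
}

#' @export
print.pm_series <- function(x, ...) {
  cat(sprintf("<pm_series> %s (%s, %s), %d records at %ds cadence\n",
              x$unit_id, x$instrument_kind, x$size_fraction,
              nrow(x$data), as.integer(x$cadence_s)))
  if (nrow(x$data)) {
    rng <- range(x$data$timestamp)
    cat("  span:", fmt_ts(rng[1]), "to", fmt_ts(rng[2]), "\n")
  }
  invisible(x)
}

#' Read an instrument log file
#'
#' Parses one of the three CSV log dialects (comma-separated, one header
#' line, `.` decimal, ISO-8601 timestamps `YYYY-MM-DDTHH:MM:SS`):
#' \describe{
#'   \item{wearable}{columns `timestamp,pm1,pm2_5,pm10,n_gt_0_3,n_gt_0_5,
#'     n_gt_1_0,n_gt_2_5,n_gt_5_0,n_gt_10,temp_c,rh_pct,lat,lon`
#'     (`lat`/`lon` may be empty for indoor use).}
#'   \item{teom / comparison}{columns `timestamp,value`, preceded by a
#'     metadata comment line `# unit_id=...,size_fraction=...`.}
#' }
#' All records are validated (see [pm_series()]); malformed rows raise an
#' error naming the file line.
#'
#' @param path File to read.
#' @param dialect `"wearable"`, `"teom"`, or `"comparison"`.
#' @param unit_id Override the unit label (defaults to the sidecar metadata
#'   for teom/comparison, or the file name for wearables).
#' @return A [pm_series()].
#' @export
read_pm_log <- function(path, dialect = c("wearable", "teom", "comparison"),
                        unit_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  size_fraction <- "both"
  offset <- 1L  # header line
  if (dialect != "wearable") {
    if (!length(lines) || !startsWith(lines[1], "#"))
      stop("missing '# unit_id=...,size_fraction=...' metadata line in ", path,
           call. = FALSE)
    meta <- parse_sidecar(lines[1])
    if (is.null(unit_id)) unit_id <- meta[["unit_id"]]
    size_fraction <- meta[["size_fraction"]]
    lines <- lines[-1]
    offset <- 2L
  }
  if (is.null(unit_id)) unit_id <- sub("\\.[^.]*$", "", basename(path))
  cols <- if (dialect == "wearable") wearable_cols else c("timestamp", "value")
  if (!length(lines) || !identical(lines[1], paste(cols, collapse = ",")))
    stop("header of ", path, " does not match the ", dialect, " dialect",
         call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) {
    d <- empty_records(cols)
    return(pm_series(unit_id, dialect, size_fraction, d))
  }
  raw <- read.csv(text = c(lines[1], body), colClasses = "character",
                  check.names = FALSE)
  if (!identical(names(raw), cols) || any(is.na(raw)))
    stop("malformed row(s) in ", path, call. = FALSE)
  d <- data.frame(timestamp = parse_ts(raw$timestamp))
  if (any(is.na(d$timestamp)))
    stop("malformed timestamp at line ",
         which(is.na(d$timestamp))[1] + offset, " of ", path, call. = FALSE)
  optional <- c("lat", "lon")
  for (col in setdiff(cols, "timestamp")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) & !(col %in% optional & raw[[col]] == "")
    if (any(bad))
      stop("malformed ", col, " at line ", which(bad)[1] + offset, " of ",
           path, call. = FALSE)
    d[[col]] <- v
  }
  pm_series(unit_id, dialect, size_fraction, d)
}

parse_sidecar <- function(line) {
  s <- sub("^#\\s*", "", line)
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) trimws(p[2]), "")
  names(vals) <- vapply(kv, function(p) trimws(p[1]), "")
  if (!all(c("unit_id", "size_fraction") %in% names(vals)))
    stop("sidecar metadata must name unit_id and size_fraction", call. = FALSE)
  vals
}

empty_records <- function(cols) {
  d <- data.frame(timestamp = as.POSIXct(character(), tz = "UTC"))
  for (col in setdiff(cols, "timestamp")) d[[col]] <- numeric()
  d
}

#' Write an instrument log file
#'
#' Emits the canonical CSV dialect for the series' instrument kind (see
#' [read_pm_log()]); `read_pm_log(write_pm_log(s))` reproduces `s` exactly,
#' and re-writing a file read with `read_pm_log()` reproduces it
#' byte-for-byte. Missing GPS fields are written as empty strings.
#'
#' @param series A [pm_series()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_pm_log <- function(series, path) {
  stopifnot(inherits(series, "pm_series"))
  d <- series$data
  cols <- names(d)
  header <- paste(cols, collapse = ",")
  fields <- lapply(cols, function(col)
    if (col == "timestamp") fmt_ts(d[[col]]) else fmt_num(d[[col]]))
  rows <- if (nrow(d)) do.call(paste, c(fields, sep = ",")) else character()
  out <- character()
  if (series$instrument_kind != "wearable")
    out <- sprintf("# unit_id=%s,size_fraction=%s",
                   series$unit_id, series$size_fraction)
  writeLines(c(out, header, rows), path)
  invisible(path)
}

#' Average a series onto a 1-minute grid
#'
#' Computes the arithmetic mean of all samples whose timestamps fall in
#' `[minute, minute + 60 s)` for each covered minute, mirroring the 1-min
#' averaged reference data used for steady-state screening. A minute is
#' flagged `complete` only when it holds at least 75% of the samples its
#' cadence implies (>= 9 of 12 at 5-s cadence); incomplete minutes are
#' excluded from downstream rolling-CV windows.
#'
#' @param series A [pm_series()].
#' @param channel Column to average: `"value"` for reference/comparison
#'   series (the default there), or one of the mass channels (`"pm2_5"`,
#'   `"pm10"`, ...) for wearables.
#' @return A data frame with columns `minute_start` (`POSIXct`), `value`,
#'   `n_samples`, `complete`. Empty input gives zero rows.
#' @export
resample_to_minutes <- function(series, channel = NULL) {
  stopifnot(inherits(series, "pm_series"))
  if (is.null(channel))
    channel <- if (series$instrument_kind == "wearable") "pm2_5" else "value"
  if (!channel %in% names(series$data))
    stop("channel '", channel, "' not present in series", call. = FALSE)
  d <- series$data
  if (!nrow(d))
    return(data.frame(minute_start = as.POSIXct(character(), tz = "UTC"),
                      value = numeric(), n_samples = integer(),
                      complete = logical()))
  minute <- as.POSIXct(floor(as.numeric(d$timestamp) / 60) * 60,
                       origin = "1970-01-01", tz = "UTC")
  v <- d[[channel]]
  agg <- tapply(v, as.numeric(minute), mean)
  n <- tapply(v, as.numeric(minute), length)
  ord <- order(as.numeric(names(agg)))
  expected <- 60 / series$cadence_s
  out <- data.frame(
    minute_start = as.POSIXct(as.numeric(names(agg))[ord],
                              origin = "1970-01-01", tz = "UTC"),
    value = as.numeric(agg)[ord],
    n_samples = as.integer(n)[ord])
  out$complete <- out$n_samples >= ceiling(0.75 * expected)
  rownames(out) <- NULL
  out
}
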