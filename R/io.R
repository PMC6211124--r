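# CSV input/output for recordings, ground truth and detected steps.

#' Read an accelerometer recording from CSV
#'
#' Reads a plain CSV with a time column and three acceleration columns,
#' resolves columns through `column_map`, auto-detects units unless given,
#' and returns a uniformly sampled [accel_series()] in g units. If the
#' source timestamps are irregular by more than 1% the series is resampled
#' onto a uniform grid at the declared rate by linear interpolation.
#'
#' @param path Path to a CSV file with a header row.
#' @param column_map Named character vector mapping roles to column names;
#'   default `c(t = "t", x = "x", y = "y", z = "z")`. The `t` entry may name
#'   a missing column if `fs_hint` is given.
#' @param fs_hint Sampling rate in Hz, required when the file has no usable
#'   time column; otherwise used as the authoritative rate.
#' @param units `"g"`, `"m_per_s2"`, or `NULL` to auto-detect from resting
#'   magnitude via [detect_units()].
#' @return An [accel_series()] in g units.
#' @export
read_accel_csv <- function(path,
                           column_map = c(t = "t", x = "x", y = "y", z = "z"),
                           fs_hint = NULL, units = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  defaults <- c(t = "t", x = "x", y = "y", z = "z")
  map <- defaults
  map[names(column_map)] <- column_map
  df <- utils::read.csv(path, check.names = FALSE)
  need <- map[c("x", "y", "z")]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("missing acceleration column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ax <- as.numeric(df[[map["x"]]])
  ay <- as.numeric(df[[map["y"]]])
  az <- as.numeric(df[[map["z"]]])
  has_t <- map["t"] %in% names(df)
  if (!has_t && is.null(fs_hint))
    stop("no time column '", map["t"], "' and no fs_hint given", call. = FALSE)

  if (has_t) {
    t <- as.numeric(df[[map["t"]]])
    if (any(diff(t) <= 0)) stop("time column is not strictly increasing",
                                call. = FALSE)
    fs <- if (is.null(fs_hint)) 1 / stats::median(diff(t)) else fs_hint
    dt <- diff(t)
    irregular <- max(abs(dt - 1 / fs)) / (1 / fs) > 0.01
    if (irregular) {
      gap_ratio <- mean(dt > 1.5 / fs)
      if (gap_ratio > 0.05)
        warning(sprintf("%.1f%% of sampling intervals are gaps (> 1.5/fs); ",
                        gap_ratio * 100),
                "interpolated values may be unreliable", call. = FALSE)
      message(sprintf("irregular timestamps: resampling to uniform %g Hz grid",
                      fs))
      tu <- seq(t[1], t[length(t)], by = 1 / fs)
      ax <- stats::approx(t, ax, xout = tu)$y
      ay <- stats::approx(t, ay, xout = tu)$y
      az <- stats::approx(t, az, xout = tu)$y
      t <- tu
    }
  } else {
    fs <- fs_hint
    t <- seq(0, by = 1 / fs, length.out = length(ax))
  }

  series <- accel_series(t, ax, ay, az, fs = fs, units = "g")
  series$units <- if (is.null(units)) detect_units(series) else
    match.arg(units, c("g", "m_per_s2"))
  series$source_units <- series$units
  normalize_units(series)
}

#' Write detected steps to CSV
#'
#' Writes one row per confirmed step with columns `step_index`, `time_s`,
#' `state`, `peak_amplitude_g`. An empty step table produces a header-only
#' file.
#'
#' @param steps A step-event data frame as returned by [validate_steps()] or
#'   found in `count_steps()$steps`.
#' @param path Output file path.
#' @export
write_steps <- function(steps, path) {
  out <- data.frame(
    step_index = if (nrow(steps)) seq_len(nrow(steps)) else integer(0),
    time_s = steps$time,
    state = as.character(steps$state),
    peak_amplitude_g = steps$amplitude
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a step CSV written by [write_steps()]
#'
#' @param path Path to a step CSV.
#' @return Data frame with columns `time`, `state`, `amplitude`.
#' @export
read_steps <- function(path) {
  df <- utils::read.csv(path)
  data.frame(time = df$time_s, state = df$state, amplitude = df$peak_amplitude_g)
}
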