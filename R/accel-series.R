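# Core containers: tri-axial acceleration series and ground-truth annotations.

STANDARD_GRAVITY <- 9.80665

#' Construct a tri-axial acceleration series
#'
#' The central input container of the package: a uniformly sampled tri-axial
#' accelerometer recording. Internally all processing is done in g units
#' (multiples of standard gravity, 9.80665 m/s^2), so that a device at rest
#' has vector magnitude 1 regardless of orientation.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing on a
#'   (near-)uniform grid. May be `NULL`, in which case a grid starting at 0
#'   with spacing `1/fs` is generated.
#' @param ax,ay,az Numeric vectors of acceleration samples along the three
#'   device axes, same length as `t`.
#' @param fs Sampling rate in Hz. If `NULL`, inferred as `1/median(diff(t))`.
#' @param units Units of the input samples: `"g"` or `"m_per_s2"`. Samples in
#'   m/s^2 are kept as given; call [normalize_units()] to convert to g.
#' @param validate Check invariants (lengths, monotone time, grid regularity).
#'
#' @return An object of class `accel_series`: a list with fields `t`, `ax`,
#'   `ay`, `az`, `fs`, `units`, `source_units`.
#' @seealso [read_accel_csv()], [magnitude()], [normalize_units()]
#' @export
accel_series <- function(t = NULL, ax, ay, az, fs = NULL,
                         units = c("g", "m_per_s2"), validate = TRUE) {
  units <- match.arg(units)
  n <- length(ax)
  if (length(ay) != n || length(az) != n)
    stop("ax, ay, az must have equal length", call. = FALSE)
  if (is.null(t)) {
    if (is.null(fs)) stop("supply either t or fs", call. = FALSE)
    t <- seq(0, by = 1 / fs, length.out = n)
  }
  if (length(t) != n)
    stop("t must have the same length as the acceleration columns", call. = FALSE)
  if (is.null(fs)) {
    if (n < 2) stop("cannot infer fs from fewer than 2 samples", call. = FALSE)
    fs <- 1 / stats::median(diff(t))
  }
  x <- structure(
    list(t = as.numeric(t), ax = as.numeric(ax), ay = as.numeric(ay),
         az = as.numeric(az), fs = as.numeric(fs), units = units,
         source_units = units),
    class = "accel_series"
  )
  if (validate && n > 0) validate_accel_series(x)
  x
}

validate_accel_series <- function(x) {
  n <- length(x$t)
  if (n < 2) stop("accel_series needs at least 2 samples", call. = FALSE)
  dt <- diff(x$t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  nominal <- 1 / x$fs
  if (abs(stats::median(dt) - nominal) / nominal >= 0.01)
    stop("median sampling interval deviates from 1/fs by >= 1%; ",
         "resample first (see read_accel_csv)", call. = FALSE)
  invisible(x)
}

#' @export
print.accel_series <- function(x, ...) {
  n <- length(x$t)
  dur <- if (n > 0) x$t[n] - x$t[1] else 0
  cat(sprintf("<accel_series> %d samples, %.1f s at %g Hz [%s]\n",
              n, dur, x$fs, x$units))
  invisible(x)
}

#' @export
length.accel_series <- function(x) length(x$t)

#' Auto-detect acceleration units from resting magnitude
#'
#' Uses the fact that the vector magnitude of a (mostly) resting or walking
#' recording stays near 1 g: a median magnitude near 9.81 indicates m/s^2,
#' near 1 indicates g units.
#'
#' @param series An [accel_series()] with at least one second of data.
#' @return `"m_per_s2"` if the median magnitude lies in \[6, 14\], `"g"` if it
#'   lies in \[0.6, 1.6\]. Outside both bands an error is raised and units must
#'   be supplied explicitly.
#' @export
detect_units <- function(series) {
  stopifnot(inherits(series, "accel_series"))
  if (length(series$t) < series$fs)
    stop("need at least 1 s of data to detect units", call. = FALSE)
  m <- stats::median(sqrt(series$ax^2 + series$ay^2 + series$az^2))
  if (m >= 6 && m <= 14) return("m_per_s2")
  if (m >= 0.6 && m <= 1.6) return("g")
  stop(sprintf(paste0("cannot detect units: median magnitude %.3g is outside ",
                      "both the g band [0.6, 1.6] and the m/s^2 band [6, 14]; ",
                      "supply units explicitly"), m), call. = FALSE)
}

#' Convert an acceleration series to g units
#'
#' Divides all axes by standard gravity (9.80665 m/s^2) when the series is in
#' m/s^2; a series already in g is returned unchanged, so the operation is
#' idempotent.
#'
#' @param series An [accel_series()].
#' @return The series in g units, with `source_units` preserved.
#' @export
normalize_units <- function(series) {
  stopifnot(inherits(series, "accel_series"))
  if (series$units == "g") return(series)
  series$ax <- series$ax / STANDARD_GRAVITY
  series$ay <- series$ay / STANDARD_GRAVITY
  series$az <- series$az / STANDARD_GRAVITY
  series$units <- "g"
  series
}

#' Ground-truth step annotation
#'
#' @param true_step_count Non-negative integer: the number of steps actually
#'   executed in the recording.
#' @param step_times Optional numeric vector of per-step times in seconds,
#'   strictly increasing, of length `true_step_count`.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(true_step_count, step_times = NULL) {
  true_step_count <- as.integer(true_step_count)
  if (is.na(true_step_count) || true_step_count < 0)
    stop("true_step_count must be a non-negative integer", call. = FALSE)
  if (!is.null(step_times)) {
    if (length(step_times) != true_step_count)
      stop("step_times must have length true_step_count", call. = FALSE)
    if (true_step_count > 1 && any(diff(step_times) <= 0))
      stop("step_times must be strictly increasing", call. = FALSE)
  }
  structure(list(true_step_count = true_step_count,
                 step_times = step_times),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d steps%s\n", x$true_step_count,
              if (is.null(x$step_times)) "" else " (with times)"))
  invisible(x)
}
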