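# Phase 2: walking-state classification and per-state parameter bundles.

#' @rdname classify_state
#' @export
MOTION_STATES <- c("slow", "normal", "fast")

# Per-state defaults. d is the minimal peak distance in samples at 50 Hz;
# H the minimal peak prominence (g); th_vib the vibration-elimination
# threshold (g); Ts the mean step period (s). Thresholds rise with walking
# intensity; d falls because fast steps are closer together.
STATE_DEFAULTS <- list(
  slow   = list(d = 14L, H = 0.20, th_vib = 0.08, Ts = 0.635),
  normal = list(d = 12L, H = 0.25, th_vib = 0.10, Ts = 0.507),
  fast   = list(d = 10L, H = 0.35, th_vib = 0.15, Ts = 0.469)
)

#' Classifier configuration for walking states
#'
#' Walking intensity is separated by the mean of the filtered magnitude in a
#' sliding window: fast walking has the largest mean magnitude, slow walking
#' the smallest. `M1` and `M2` are the two boundaries in g units. The
#' defaults are calibrated to the synthetic gait generator's per-state
#' magnitude distributions at its default amplitudes (see the package
#' vignette); for real devices they should be treated as tuning parameters
#' and set from a short labelled recording.
#'
#' @param M1 Slow/normal boundary in g; must satisfy `0 < M1 < M2`.
#' @param M2 Normal/fast boundary in g.
#' @param window_s Classification window length in seconds (50% overlap).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(M1 = 1.145, M2 = 1.185, window_s = 2.0) {
  if (!(M1 > 0 && M1 < M2))
    stop("require 0 < M1 < M2", call. = FALSE)
  if (window_s <= 0) stop("window_s must be positive", call. = FALSE)
  structure(list(M1 = M1, M2 = M2, window_s = window_s),
            class = "classifier_config")
}

#' Sliding-window mean magnitude
#'
#' Mean of the magnitude over windows of `window_s` seconds with 50%
#' overlap; the classification feature for walking state. A series shorter
#' than one window yields its single whole-series mean.
#'
#' @param mag A `magnitude_series` (normally filtered).
#' @param window_s Window length in seconds; `window_s * fs` must be >= 2.
#' @return Data frame with columns `time` (window center) and `mean_mag` (g).
#' @export
window_mean_magnitude <- function(mag, window_s = 2.0) {
  stopifnot(inherits(mag, "magnitude_series"))
  if (window_s <= 0) stop("window_s must be positive", call. = FALSE)
  w <- round(window_s * mag$fs)
  if (w < 2) stop("window_s * fs must be at least 2", call. = FALSE)
  n <- length(mag$acc)
  if (n < w) {
    return(data.frame(time = mean(mag$t), mean_mag = mean(mag$acc)))
  }
  hop <- max(1L, floor(w / 2))
  starts <- unique(c(seq(1L, n - w + 1L, by = hop), n - w + 1L))
  cs <- c(0, cumsum(mag$acc))
  means <- (cs[starts + w] - cs[starts]) / w
  centers <- mag$t[starts] + (w - 1) / (2 * mag$fs)
  data.frame(time = centers, mean_mag = means)
}

#' Classify walking state from mean magnitude
#'
#' @param mean_mag Mean magnitude in g (vectorized).
#' @param cfg A [classifier_config()].
#' @return Character vector of states: `"slow"` if `mean_mag < M1`,
#'   `"normal"` if `M1 <= mean_mag < M2`, `"fast"` otherwise (half-open
#'   intervals, so `mean_mag == M2` is fast).
#' @export
classify_state <- function(mean_mag, cfg = classifier_config()) {
  stopifnot(all(mean_mag >= 0))
  ifelse(mean_mag < cfg$M1, "slow",
         ifelse(mean_mag < cfg$M2, "normal", "fast"))
}

#' Per-state detection parameter bundle
#'
#' Returns the parameter set used by the peak-detection stage for one
#' walking state: minimal peak distance `d` (samples), minimal peak
#' prominence `H` (g), vibration threshold `th_vib` (g), mean step period
#' `Ts` (s), and the analysis window `win_size = round(Ts * fs) - 1`
#' (samples) shared by the prominence and dynamic-thresholding stages.
#'
#' @param state One of `"slow"`, `"normal"`, `"fast"`.
#' @param fs Sampling rate in Hz.
#' @param overrides Named list replacing any of `d`, `H`, `th_vib`, `Ts`,
#'   `win_size`.
#' @return A `state_profile` list.
#' @examples
#' profile_for("normal", 50)   # d = 12, H = 0.25 g, win_size = 24
#' @export
profile_for <- function(state, fs, overrides = list()) {
  state <- match.arg(state, MOTION_STATES)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  p <- STATE_DEFAULTS[[state]]
  p$win_size <- as.integer(round(p$Ts * fs) - 1)
  bad <- setdiff(names(overrides), c("d", "H", "th_vib", "Ts", "win_size"))
  if (length(bad))
    stop("unknown profile override(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if ("Ts" %in% names(overrides) && !("win_size" %in% names(overrides)))
    p$win_size <- as.integer(round(overrides$Ts * fs) - 1)
  p[names(overrides)] <- overrides
  if (p$d < 1) stop("d must be >= 1", call. = FALSE)
  if (p$win_size < 3) stop("win_size must be >= 3", call. = FALSE)
  if (p$H <= 0 || p$th_vib <= 0 || p$Ts <= 0)
    stop("H, th_vib and Ts must be positive", call. = FALSE)
  structure(c(list(state = state, fs = fs), p), class = "state_profile")
}

#' @export
print.state_profile <- function(x, ...) {
  cat(sprintf(
    "<state_profile> %s: d=%d, H=%.2f g, th_vib=%.2f g, Ts=%.3f s, win_size=%d\n",
    x$state, x$d, x$H, x$th_vib, x$Ts, x$win_size))
  invisible(x)
}
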