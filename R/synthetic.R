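# Parametric synthetic gait generator with exact ground truth.
#
# The magnitude model is a 1 g baseline plus one raised-cosine impact pulse
# per step, a shallower raised-cosine dip at mid-stride (the deceleration
# trough real gait shows between foot strikes), a small second-harmonic
# ripple, and white Gaussian noise. The scalar profile is embedded into the
# three axes through one fixed random unit orientation per recording, so the
# RMS magnitude recovers it exactly. This is a signal model for exercising
# the detector, not a biomechanical gait model.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# unit-height raised-cosine bump of total support w centered at 0
raised_cosine <- function(u, w) {
  ifelse(abs(u) <= w / 2, 0.5 * (1 + cos(2 * pi * u / w)), 0)
}

DEFAULT_PEAK_AMP <- c(slow = 0.25, normal = 0.35, fast = 0.45)

#' Specification of a synthetic walking bout
#'
#' @param state Walking state; sets the default step period (the per-state
#'   means 0.635 / 0.507 / 0.469 s for slow / normal / fast) and pulse
#'   amplitude (0.25 / 0.35 / 0.45 g above baseline). The defaults keep
#'   every state's peaks above its prominence and vibration thresholds.
#' @param n_steps Number of steps (>= 0).
#' @param step_period_mean Mean step period in seconds.
#' @param step_period_cv Coefficient of variation of step periods.
#' @param peak_amp Impact-pulse height in g above the 1 g baseline.
#' @param amp_jitter Per-step amplitude jitter SD in g (clamped at 1.5 SD
#'   so clean strides stay within the similarity tolerance).
#' @param noise_sd Additive white-noise SD in g.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG stream.
#' @return A `walk_spec` list.
#' @export
walk_spec <- function(state = "normal", n_steps = 50,
                      step_period_mean = NULL, step_period_cv = 0.05,
                      peak_amp = NULL, amp_jitter = 0.03,
                      noise_sd = 0.02, seed = NULL) {
  state <- match.arg(state, MOTION_STATES)
  if (n_steps < 0) stop("n_steps must be >= 0", call. = FALSE)
  if (is.null(step_period_mean)) step_period_mean <- STATE_DEFAULTS[[state]]$Ts
  if (is.null(peak_amp)) peak_amp <- DEFAULT_PEAK_AMP[[state]]
  if (step_period_mean <= 0 || peak_amp < 0 || amp_jitter < 0 || noise_sd < 0)
    stop("invalid walk_spec: magnitudes must be non-negative and the period positive",
         call. = FALSE)
  structure(list(state = state, n_steps = as.integer(n_steps),
                 step_period_mean = step_period_mean,
                 step_period_cv = step_period_cv, peak_amp = peak_amp,
                 amp_jitter = amp_jitter, noise_sd = noise_sd, seed = seed),
            class = "walk_spec")
}

#' Specification of a synthetic false-walking bout
#'
#' Device motion without locomotion. `vehicle_vibration` and `leg_tremor`
#' emit band-limited noise around 1 g whose amplitude stays below every
#' state's vibration threshold; `hand_motion` and `pocket_insertion` emit
#' isolated impact-like transients with aperiodic spacing (gaps of
#' 0.9–2.0 s, outside the step-period band). Ground truth is always 0
#' steps.
#'
#' @param kind One of `"hand_motion"`, `"pocket_insertion"`,
#'   `"vehicle_vibration"`, `"leg_tremor"`.
#' @param duration Recording length in seconds (vibration kinds; transient
#'   kinds derive their length from the event spacing, with `duration` as a
#'   minimum).
#' @param vib_amp Peak deviation from 1 g for vibration kinds, in g; must
#'   stay below the smallest state vibration threshold (0.08 g).
#' @param n_pseudo_events Number of transients for transient kinds.
#' @param seed Integer RNG seed, or `NULL`.
#' @return A `false_walk_spec` list.
#' @export
false_walk_spec <- function(kind = c("hand_motion", "pocket_insertion",
                                     "vehicle_vibration", "leg_tremor"),
                            duration = 30, vib_amp = 0.05,
                            n_pseudo_events = 30, seed = NULL) {
  kind <- match.arg(kind)
  if (duration < 0) stop("duration must be >= 0", call. = FALSE)
  if (kind %in% c("vehicle_vibration", "leg_tremor") && vib_amp >= 0.08)
    stop("vib_amp must stay below the smallest vibration threshold (0.08 g)",
         call. = FALSE)
  if (n_pseudo_events < 0) stop("n_pseudo_events must be >= 0", call. = FALSE)
  structure(list(kind = kind, duration = duration, vib_amp = vib_amp,
                 n_pseudo_events = as.integer(n_pseudo_events), seed = seed),
            class = "false_walk_spec")
}

# embed a non-negative scalar magnitude profile into three axes through a
# random fixed orientation; the RMS magnitude recovers it exactly
embed_axes <- function(m, fs, t0 = 0) {
  v <- stats::rnorm(3)
  v <- v / sqrt(sum(v^2))
  t <- seq(t0, by = 1 / fs, length.out = length(m))
  accel_series(t, m * v[1], m * v[2], m * v[3], fs = fs, units = "g",
               validate = length(m) >= 2)
}

#' Generate a synthetic walking bout
#'
#' @param spec A [walk_spec()].
#' @param fs Sampling rate in Hz (>= 20).
#' @return A list with `series` (an [accel_series()] in g units), `truth`
#'   (a [ground_truth()] whose `step_times` are the exact pulse centers),
#'   and `model` (the noiseless magnitude profile, for self-consistency
#'   checks).
#' @export
generate_walk <- function(spec, fs = 50) {
  stopifnot(inherits(spec, "walk_spec"))
  if (fs < 20) stop("fs must be >= 20 Hz", call. = FALSE)
  with_seed(spec$seed, {
    lead <- 0.5
    Tm <- spec$step_period_mean
    K <- spec$n_steps
    if (K == 0) {
      n <- round(2 * lead * fs)
      m0 <- rep(1, n)
      m <- pmax(m0 + stats::rnorm(n, 0, spec$noise_sd), 0)
      return(list(series = embed_axes(m, fs),
                  truth = ground_truth(0, numeric(0)), model = m0))
    }
    z <- pmax(pmin(stats::rnorm(K), 2.5), -2.5)
    periods <- Tm * (1 + spec$step_period_cv * z)
    step_times <- lead + cumsum(c(0, periods[-K]))
    zh <- pmax(pmin(stats::rnorm(K), 1.5), -1.5)
    heights <- pmax(spec$peak_amp + spec$amp_jitter * zh, 0)

    dur <- step_times[K] + Tm + lead
    n <- round(dur * fs)
    t <- seq(0, by = 1 / fs, length.out = n)
    w_p <- 0.7 * Tm                    # impact pulse support
    w_d <- 0.5 * Tm                    # mid-stride dip support
    m0 <- rep(1, n)
    for (k in seq_len(K)) {
      m0 <- m0 + heights[k] * raised_cosine(t - step_times[k], w_p)
      dip_center <- step_times[k] + (if (k < K) periods[k] else Tm) / 2
      m0 <- m0 - 0.7 * heights[k] * raised_cosine(t - dip_center, w_d)
    }
    # sustained dynamic elevation plus second-harmonic ripple, tapered at
    # the bout boundaries; the elevation mimics the raised mean RMS that an
    # oscillating body acceleration produces, in proportion to intensity
    env <- pmin(1, pmax(0, (t - (step_times[1] - 0.3)) / 0.3)) *
      pmin(1, pmax(0, ((step_times[K] + 0.3) - t) / 0.3))
    m0 <- m0 + (0.3 * spec$peak_amp +
                0.1 * spec$peak_amp * sin(4 * pi * (t - step_times[1]) / Tm)) * env
    m <- pmax(m0 + stats::rnorm(n, 0, spec$noise_sd), 0)
    list(series = embed_axes(m, fs),
         truth = ground_truth(K, step_times), model = m0)
  })
}

#' Generate a synthetic false-walking bout
#'
#' @param spec A [false_walk_spec()].
#' @param fs Sampling rate in Hz (>= 20).
#' @return A list with `series`, `truth` (always 0 steps), and
#'   `pseudo_event_times` (transient centers, empty for vibration kinds).
#' @export
generate_false_walk <- function(spec, fs = 50) {
  stopifnot(inherits(spec, "false_walk_spec"))
  if (fs < 20) stop("fs must be >= 20 Hz", call. = FALSE)
  with_seed(spec$seed, {
    if (spec$duration == 0) {
      s <- accel_series(numeric(0), numeric(0), numeric(0), numeric(0),
                        fs = fs, units = "g", validate = FALSE)
      return(list(series = s, truth = ground_truth(0),
                  pseudo_event_times = numeric(0)))
    }
    if (spec$kind %in% c("vehicle_vibration", "leg_tremor")) {
      n <- round(spec$duration * fs)
      band <- if (spec$kind == "vehicle_vibration") 8 else 6  # Hz
      b <- signal::butter(2, min(band / (fs / 2), 0.9), type = "low")
      e <- as.numeric(signal::filter(b, stats::rnorm(4 * n)))[-(1:(3 * n))]
      e <- e / stats::sd(e) * spec$vib_amp / 2
      e <- pmax(pmin(e, spec$vib_amp), -spec$vib_amp)
      m <- pmax(1 + e, 0)
      return(list(series = embed_axes(m, fs), truth = ground_truth(0),
                  pseudo_event_times = numeric(0)))
    }
    # transient kinds: aperiodic impact-like spikes around handling events
    K <- spec$n_pseudo_events
    if (K == 0) {
      n <- max(2, round(max(spec$duration, 1) * fs))
      m <- pmax(1 + stats::rnorm(n, 0, 0.01), 0)
      return(list(series = embed_axes(m, fs), truth = ground_truth(0),
                  pseudo_event_times = numeric(0)))
    }
    gaps <- stats::runif(K, 0.9, 2.0)
    centers <- 0.5 + cumsum(gaps)
    amps <- stats::runif(K, 0.2, 0.9)
    widths <- stats::runif(K, 0.04, 0.09)
    dur <- max(spec$duration, centers[K] + 1)
    n <- round(dur * fs)
    t <- seq(0, by = 1 / fs, length.out = n)
    m0 <- rep(1, n)
    for (k in seq_len(K))
      m0 <- m0 + amps[k] * raised_cosine(t - centers[k], widths[k])
    m <- pmax(m0 + stats::rnorm(n, 0, 0.01), 0)
    list(series = embed_axes(m, fs), truth = ground_truth(0),
         pseudo_event_times = centers)
  })
}

#' Generate a multi-segment synthetic session
#'
#' Concatenates walking and false-walking segments, separated by 0.5 s
#' still gaps (1 g plus a 0.005 g noise floor), into one recording with a
#' combined ground truth. Emulates free walking as a mixture of cadences
#' and pauses.
#'
#' @param segments List of [walk_spec()] / [false_walk_spec()] objects.
#' @param fs Sampling rate in Hz.
#' @param gap_s Still-gap length between segments in seconds.
#' @return A list with `series`, `truth` (summed counts, globally timed
#'   step times), and `segment_table` (per-segment start time and count).
#' @export
generate_session <- function(segments, fs = 50, gap_s = 0.5) {
  if (length(segments) == 0) stop("need at least one segment", call. = FALSE)
  m_all <- numeric(0)
  times_all <- numeric(0)
  total <- 0L
  seg_start <- numeric(length(segments))
  seg_count <- integer(length(segments))
  gap_n <- round(gap_s * fs)
  for (s in seq_along(segments)) {
    spec <- segments[[s]]
    g <- if (inherits(spec, "walk_spec")) generate_walk(spec, fs)
         else generate_false_walk(spec, fs)
    mseg <- sqrt(g$series$ax^2 + g$series$ay^2 + g$series$az^2)
    offset <- length(m_all) / fs
    seg_start[s] <- offset
    seg_count[s] <- g$truth$true_step_count
    if (!is.null(g$truth$step_times))
      times_all <- c(times_all, g$truth$step_times + offset)
    total <- total + g$truth$true_step_count
    m_all <- c(m_all, mseg)
    if (s < length(segments)) {
      gap_noise <- with_seed(
        if (is.null(spec$seed)) NULL else spec$seed + 1000003L,
        stats::rnorm(gap_n, 0, 0.005))
      m_all <- c(m_all, pmax(1 + gap_noise, 0))
    }
  }
  first_seed <- segments[[1]]$seed
  series <- with_seed(if (is.null(first_seed)) NULL else first_seed + 2000003L,
                      embed_axes(m_all, fs))
  list(series = series,
       truth = ground_truth(total, if (length(times_all)) times_all else NULL),
       segment_table = data.frame(start_s = seg_start, steps = seg_count))
}
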