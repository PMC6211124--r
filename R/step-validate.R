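# Phase 4: step confirmation by periodicity and similarity; the full
# pipeline orchestrator; error/accuracy metrics.

#' Validation configuration
#'
#' @param t_min,t_max Accepted inter-step interval band in seconds. Step
#'   periods across slow, normal and fast walking lie in roughly
#'   0.45–0.65 s; the default band \[0.35, 0.80\] widens that range ~25%
#'   to tolerate inter-subject cadence variability.
#' @param s_tol Similarity tolerance in g: the largest allowed amplitude
#'   difference between a peak and the previous peak of the same leg (the
#'   second-to-last confirmed step). Same-leg strides are nearly equal in
#'   amplitude; spurious high peaks are not.
#' @return A `validation_config` list.
#' @export
validation_config <- function(t_min = 0.35, t_max = 0.80, s_tol = 0.3) {
  if (!(t_min > 0 && t_min < t_max))
    stop("require 0 < t_min < t_max", call. = FALSE)
  if (s_tol <= 0) stop("s_tol must be positive", call. = FALSE)
  structure(list(t_min = t_min, t_max = t_max, s_tol = s_tol),
            class = "validation_config")
}

#' Inter-peak period from sample indices
#'
#' @param index_a,index_b Sample indices of two peaks, `index_b > index_a`.
#' @param fs Sampling rate in Hz.
#' @return `(index_b - index_a) / fs`, the interval in seconds.
#' @export
periodicity <- function(index_a, index_b, fs) {
  if (any(index_b <= index_a))
    stop("index_b must exceed index_a", call. = FALSE)
  (index_b - index_a) / fs
}

#' Same-leg amplitude similarity
#'
#' The similarity between a peak and its second-next peak (two consecutive
#' peaks of the *same* leg), defined as the negated absolute amplitude
#' difference. Values nearer 0 mean more similar; the measure is symmetric.
#'
#' @param amp_i,amp_i2 Peak amplitudes in g.
#' @return `-abs(amp_i2 - amp_i)` in g.
#' @export
similarity <- function(amp_i, amp_i2) {
  -abs(amp_i2 - amp_i)
}

#' Confirm steps from detected peaks
#'
#' Walks the Phase-3 peaks in time order and confirms each one that
#' satisfies the two false-walking checks:
#'
#' * **periodicity** — its interval to the previous confirmed step lies in
#'   `[t_min, t_max]`, or it starts a new walking bout (first peak, or the
#'   gap exceeds `t_max`, e.g. after an intermittent pause);
#' * **similarity** — its amplitude is within `s_tol` of the second-to-last
#'   confirmed step in the bout (the same leg's previous stride); waived
#'   until a bout has two confirmed steps.
#'
#' A rejected peak is dropped on its own: it never cascades into removing
#' previously confirmed steps, which is what makes the validator robust to
#' isolated spurious peaks in noisy low-cost sensor data.
#'
#' @param peaks Peak data frame from [detect_peaks()] (time-ordered).
#' @param cfg A [validation_config()].
#' @param fs Sampling rate in Hz; intervals are computed from sample
#'   indices divided by `fs`.
#' @return Data frame of confirmed steps with columns `time`, `state`,
#'   `amplitude`, `index`, `interval_prev` (NA at bout starts).
#' @export
validate_steps <- function(peaks, cfg = validation_config(), fs) {
  stopifnot(inherits(cfg, "validation_config"))
  empty <- data.frame(time = numeric(0), state = character(0),
                      amplitude = numeric(0), index = integer(0),
                      interval_prev = numeric(0))
  if (is.null(peaks) || nrow(peaks) == 0) return(empty)
  if (is.unsorted(peaks$index, strictly = TRUE))
    stop("peaks must be strictly ordered in time", call. = FALSE)

  conf_idx <- integer(0)      # indices into `peaks` of confirmed steps
  bout_len <- 0L              # confirmed steps in the current bout
  interval_prev <- rep(NA_real_, nrow(peaks))
  for (p in seq_len(nrow(peaks))) {
    if (length(conf_idx) == 0) {
      gap <- Inf
    } else {
      gap <- periodicity(peaks$index[conf_idx[length(conf_idx)]],
                         peaks$index[p], fs)
    }
    if (gap > cfg$t_max) {
      # bout start (first peak ever, or resumption after a pause)
      conf_idx <- c(conf_idx, p)
      bout_len <- 1L
      next
    }
    if (gap < cfg$t_min) next  # too close to the previous step: reject
    if (bout_len >= 2L) {
      same_leg <- peaks$amplitude[conf_idx[length(conf_idx) - 1L]]
      if (-similarity(same_leg, peaks$amplitude[p]) > cfg$s_tol) next
    }
    interval_prev[p] <- gap
    conf_idx <- c(conf_idx, p)
    bout_len <- bout_len + 1L
  }
  if (length(conf_idx) == 0) return(empty)
  out <- data.frame(time = peaks$time[conf_idx],
                    state = as.character(peaks$state[conf_idx]),
                    amplitude = peaks$amplitude[conf_idx],
                    index = peaks$index[conf_idx],
                    interval_prev = interval_prev[conf_idx])
  rownames(out) <- NULL
  out
}

#' Count steps in an accelerometer recording
#'
#' Runs the full pipeline: RMS magnitude and 3 Hz zero-phase low-pass
#' (Phase 1); sliding-window walking-state classification (Phase 2);
#' state-adaptive peak detection on each contiguous same-state segment
#' (Phase 3); periodicity/similarity step confirmation (Phase 4).
#'
#' @param series An [accel_series()] (any units; converted to g).
#' @param config A [step_config()] bundle of all pipeline parameters.
#' @return An object of class `step_count` with fields `steps` (confirmed
#'   step data frame), `n_steps`, `per_state` (named count vector), `peaks`
#'   (Phase-3 survivors), `windows` (per-window state table), and
#'   `magnitude` (the filtered magnitude series).
#' @export
count_steps <- function(series, config = step_config()) {
  stopifnot(inherits(series, "accel_series"))
  series <- normalize_units(series)
  filt <- lowpass(magnitude(series), cutoff = config$cutoff)
  n <- length(filt$acc)

  wm <- window_mean_magnitude(filt, config$classifier$window_s)
  if (identical(config$state, "auto")) {
    wm$state <- classify_state(wm$mean_mag, config$classifier)
  } else {
    wm$state <- rep(config$state, nrow(wm))
  }

  # each sample takes the state of the nearest window center
  centers_idx <- round((wm$time - filt$t[1]) * filt$fs) + 1
  nearest <- findInterval(seq_len(n), c(-Inf, (centers_idx[-1] + centers_idx[-length(centers_idx)]) / 2))
  sample_state <- wm$state[nearest]

  # run detection once per state present over the whole series, then keep
  # each peak under the profile of its own sample's state; detecting on the
  # full signal avoids losing peaks within d samples of a state boundary
  peaks <- NULL
  for (st in intersect(MOTION_STATES, unique(sample_state))) {
    prof <- profile_for(st, filt$fs, config$profile_overrides[[st]])
    cfg_d <- dynamic_threshold_config(config$th_d, prof$win_size)
    pk <- detect_peaks(filt, prof, cfg_d)
    pk <- pk[sample_state[pk$index] == st, , drop = FALSE]
    if (nrow(pk) > 0) peaks <- rbind(peaks, pk)
  }
  if (!is.null(peaks)) peaks <- peaks[order(peaks$index), , drop = FALSE]

  steps <- validate_steps(peaks, config$validation, filt$fs)
  per_state <- vapply(MOTION_STATES,
                      function(s) sum(steps$state == s), integer(1))
  structure(list(steps = steps, n_steps = nrow(steps),
                 per_state = per_state, peaks = peaks,
                 windows = wm, magnitude = filt),
            class = "step_count")
}

#' @export
print.step_count <- function(x, ...) {
  cat(sprintf("<step_count> %d steps (slow %d, normal %d, fast %d)\n",
              x$n_steps, x$per_state[["slow"]], x$per_state[["normal"]],
              x$per_state[["fast"]]))
  invisible(x)
}

#' Full pipeline configuration
#'
#' Bundles every tunable parameter of [count_steps()]. All thresholds are
#' in g units; see the component constructors for meaning and defaults.
#'
#' @param cutoff Low-pass cutoff in Hz.
#' @param classifier A [classifier_config()].
#' @param th_d Dynamic-threshold margin in g.
#' @param validation A [validation_config()].
#' @param state `"auto"` for per-window classification, or one of
#'   `"slow"`, `"normal"`, `"fast"` to force a single state.
#' @param profile_overrides Named list (by state) of [profile_for()]
#'   override lists, e.g. `list(normal = list(d = 10))`.
#' @return A `step_config` list.
#' @export
step_config <- function(cutoff = 3.0, classifier = classifier_config(),
                        th_d = 0.15, validation = validation_config(),
                        state = "auto", profile_overrides = list()) {
  state <- match.arg(state, c("auto", MOTION_STATES))
  missing_states <- setdiff(MOTION_STATES, names(profile_overrides))
  profile_overrides[missing_states] <- list(list())
  structure(list(cutoff = cutoff, classifier = classifier, th_d = th_d,
                 validation = validation, state = state,
                 profile_overrides = profile_overrides),
            class = "step_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `cutoff`, `th_d`, `state`, a `classifier`
#' block (`M1`, `M2`, `window_s`), a `validation` block (`t_min`, `t_max`,
#' `s_tol`), and a `states` block of per-state overrides
#' (`d`, `H`, `th_vib`, `Ts`, `win_size`). Omitted keys keep their
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A [step_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cl <- do.call(classifier_config, y[["classifier"]] %||% list())
  va <- do.call(validation_config, y[["validation"]] %||% list())
  step_config(cutoff = y[["cutoff"]] %||% 3.0, classifier = cl,
              th_d = y[["th_d"]] %||% 0.15, validation = va,
              state = y[["state"]] %||% "auto",
              profile_overrides = y[["states"]] %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Step-count error and accuracy
#'
#' The relative counting error `|E - T| / T * 100` (percent) and its
#' complement, the accuracy `100 - error`.
#'
#' @param E Estimated step count (may be a non-integer mean over trials).
#' @param T_true True step count, > 0.
#' @return A list of class `eval_result` with fields `E`, `T`,
#'   `error_pct`, `accuracy_pct`.
#' @export
evaluate_steps <- function(E, T_true) {
  if (T_true <= 0)
    stop("true step count must be positive for the error metric",
         call. = FALSE)
  err <- abs(E - T_true) / T_true * 100
  structure(list(E = E, T = T_true, error_pct = err,
                 accuracy_pct = 100 - err),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> E=%g, T=%g: error %.2f%%, accuracy %.2f%%\n",
              x$E, x$T, x$error_pct, x$accuracy_pct))
  invisible(x)
}
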