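# Comparison baselines: plain peak counting, and periodicity + similarity +
# continuity with cascade elimination. Both are reconstructions of earlier
# published step counters used to contrast against the adaptive pipeline.

#' Baseline: peak counting with a fixed height threshold
#'
#' Counts candidate peaks under a minimal peak distance whose amplitude
#' exceeds a fixed height. No prominence, dynamic-threshold, vibration or
#' validation stages, so it over-counts on noisy signals and counts false
#' walking freely.
#'
#' @param mag A `magnitude_series` (normally filtered).
#' @param d Minimal peak distance in samples.
#' @param min_height Fixed height threshold in g.
#' @return Integer step count.
#' @export
count_peak_only <- function(mag, d = 12, min_height = 1.05) {
  pk <- candidate_peaks(mag, d)
  sum(pk$amplitude >= min_height)
}

#' Baseline: periodicity + similarity + continuity with cascade elimination
#'
#' Reconstructs the earlier validation scheme this package's validator was
#' designed to improve on. Candidate peaks above a fixed height are checked
#' for periodicity and same-leg similarity, but a similarity failure
#' discards *both* the offending peak and its comparison partner (the
#' cascade rule), and a continuity pass then drops bouts with fewer than
#' `min_bout` confirmed events. The cascade makes it under-count noisy true
#' walking — one spurious peak can take out true steps with it — while the
#' continuity rule makes it strong against isolated false-walking
#' transients. The continuity formula is a reconstruction (no gap beyond
#' the period band inside a bout, minimum bout length), labelled as such.
#'
#' @param mag A `magnitude_series` (normally filtered).
#' @param cfg A [validation_config()].
#' @param d Minimal peak distance in samples.
#' @param min_height Fixed height threshold in g.
#' @param min_bout Minimum number of events for a bout to count.
#' @return Integer step count.
#' @export
count_psc <- function(mag, cfg = validation_config(), d = 12,
                      min_height = 1.05, min_bout = 3L) {
  pk <- candidate_peaks(mag, d)
  pk <- pk[pk$amplitude >= min_height, , drop = FALSE]
  if (nrow(pk) == 0) return(0L)

  conf <- integer(0)   # row numbers of confirmed peaks
  bout_id <- integer(0)
  cur_bout <- 0L
  bout_len <- 0L
  for (p in seq_len(nrow(pk))) {
    gap <- if (length(conf) == 0) Inf else
      periodicity(pk$index[conf[length(conf)]], pk$index[p], mag$fs)
    if (gap > cfg$t_max) {
      cur_bout <- cur_bout + 1L
      bout_len <- 1L
      conf <- c(conf, p)
      bout_id <- c(bout_id, cur_bout)
      next
    }
    if (gap < cfg$t_min) next
    if (bout_len >= 2L) {
      partner <- length(conf) - 1L
      if (-similarity(pk$amplitude[conf[partner]], pk$amplitude[p]) > cfg$s_tol) {
        # cascade: the comparison partner is eliminated along with this peak
        conf <- conf[-partner]
        bout_id <- bout_id[-partner]
        bout_len <- bout_len - 1L
        next
      }
    }
    conf <- c(conf, p)
    bout_id <- c(bout_id, cur_bout)
    bout_len <- bout_len + 1L
  }
  if (length(conf) == 0) return(0L)
  keep <- table(bout_id)
  sum(bout_id %in% as.integer(names(keep)[keep >= min_bout]))
}

#' Run a baseline counter on a raw recording
#'
#' The plain peak counter is run on the unfiltered magnitude — it
#' reconstructs a naive counter with no signal conditioning, which is where
#' its over-counting on noisy low-cost sensors comes from. The
#' periodicity/similarity/continuity method gets the same low-pass
#' preprocessing as the adaptive pipeline.
#'
#' @param series An [accel_series()].
#' @param method `"peak_only"` or `"psc"`.
#' @param d,min_height,cfg Passed to the baseline counter.
#' @param cutoff Low-pass cutoff in Hz (psc only).
#' @return Integer step count.
#' @export
count_steps_baseline <- function(series, method = c("peak_only", "psc"),
                                 d = 12, min_height = 1.05,
                                 cfg = validation_config(), cutoff = 3.0) {
  method <- match.arg(method)
  series <- normalize_units(series)
  if (method == "peak_only")
    return(count_peak_only(magnitude(series), d = d, min_height = min_height))
  mag <- lowpass(magnitude(series), cutoff = cutoff)
  count_psc(mag, cfg = cfg, d = d, min_height = min_height)
}
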