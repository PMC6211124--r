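# Phase 3: candidate peaks and the four elimination filters.

#' Candidate peaks under a minimal peak distance
#'
#' A sample `j` is a candidate peak when `acc[j]` is >= every sample within
#' `d` positions on both sides (comparison windows are clipped at the series
#' ends). Flat-topped (plateau) maxima keep only their
#' first index, and when two qualifying peaks still fall within `d` samples
#' of each other the higher one wins (ties go to the earlier index).
#' Endpoints never qualify.
#'
#' @param mag A `magnitude_series`.
#' @param d Minimal peak distance in samples (>= 1).
#' @return Data frame with columns `index`, `time`, `amplitude`, ordered by
#'   index; empty when the series is shorter than `2d + 1`.
#' @export
candidate_peaks <- function(mag, d) {
  stopifnot(inherits(mag, "magnitude_series"))
  d <- as.integer(d)
  if (d < 1) stop("d must be >= 1", call. = FALSE)
  x <- mag$acc
  n <- length(x)
  empty <- data.frame(index = integer(0), time = numeric(0),
                      amplitude = numeric(0))
  if (n <= 2 * d) return(empty)

  # running max of the d samples on each side, built by repeated pmax on lags
  left <- x[c(1L, seq_len(n - 1L))]
  right <- x[c(seq.int(2L, n), n)]
  if (d > 1) {
    lmax <- left
    rmax <- right
    for (k in 2:d) {
      lmax <- pmax(lmax, c(rep(-Inf, k), x[seq_len(n - k)]))
      rmax <- pmax(rmax, c(x[seq.int(k + 1L, n)], rep(-Inf, k)))
    }
    left <- lmax
    right <- rmax
  }
  j <- seq.int(2L, n - 1L)   # windows clip at the ends; endpoints excluded
  ok <- j[x[j] >= left[j] & x[j] >= right[j]]
  if (length(ok) == 0) return(empty)

  # plateau: keep the first index of each run of equal-valued neighbours
  if (length(ok) > 1) {
    drop <- c(FALSE, diff(ok) == 1L & x[ok[-1]] == x[ok[-length(ok)]])
    ok <- ok[!drop]
  }

  # distance suppression: highest first, earlier index breaks ties
  ord <- ok[order(-x[ok], ok)]
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0 || all(abs(kept - i) > d)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  data.frame(index = kept, time = mag$t[kept], amplitude = x[kept])
}

#' Peak prominence within a window
#'
#' The intrinsic height of a peak: extend a horizontal line left and right
#' from the peak until each side either crosses a strictly higher sample or
#' reaches the window edge; take the minimum of the signal over each of the
#' two intervals; the prominence is the peak amplitude minus the higher of
#' the two interval minima. For the window's global maximum both intervals
#' span to the window edges.
#'
#' @param mag A `magnitude_series`.
#' @param index Sample index of the peak.
#' @param window Integer vector `c(lo, hi)` delimiting the evaluation
#'   window; defaults to the whole series.
#' @return Prominence in g units (non-negative scalar).
#' @export
peak_prominence <- function(mag, index, window = NULL) {
  stopifnot(inherits(mag, "magnitude_series"))
  x <- mag$acc
  if (is.null(window)) window <- c(1L, length(x))
  lo <- max(1L, as.integer(window[1]))
  hi <- min(length(x), as.integer(window[2]))
  i <- as.integer(index)
  if (i < lo || i > hi) stop("peak index outside window", call. = FALSE)
  h <- x[i]

  # walk outward while at or below the peak level; stop at a strictly
  # higher sample (crossing) or past the window edge
  left_min <- h
  k <- i - 1L
  while (k >= lo && x[k] <= h) {
    left_min <- min(left_min, x[k])
    k <- k - 1L
  }
  right_min <- h
  k <- i + 1L
  while (k <= hi && x[k] <= h) {
    right_min <- min(right_min, x[k])
    k <- k + 1L
  }
  h - max(left_min, right_min)
}

#' Dynamic-thresholding configuration
#'
#' @param th_d Required margin (g) of a peak over the mid-range of its
#'   window; default 0.15 g.
#' @param win_size Window length in samples (>= 3), normally taken from the
#'   state profile (`round(Ts * fs) - 1`).
#' @return A `dynamic_threshold_config` list.
#' @export
dynamic_threshold_config <- function(th_d = 0.15, win_size) {
  if (th_d <= 0) stop("th_d must be positive", call. = FALSE)
  win_size <- as.integer(win_size)
  if (win_size < 3) stop("win_size must be >= 3", call. = FALSE)
  structure(list(th_d = th_d, win_size = win_size),
            class = "dynamic_threshold_config")
}

#' Dynamic mid-range threshold filter
#'
#' For each peak, the adaptive reference `Aver_D` is the mid-range
#' `(max + min) / 2` of the magnitude over a `win_size`-sample window
#' centered on the peak (clipped at the series edges). The peak is kept when
#' its amplitude exceeds `Aver_D` by at least `th_d`. Unlike a fixed height
#' threshold this adapts to each walker's signal level.
#'
#' @param mag A `magnitude_series`.
#' @param peaks Peak data frame (needs an `index` column).
#' @param cfg A [dynamic_threshold_config()].
#' @return `peaks` with added columns `aver_d` and logical `dynamic_ok`,
#'   restricted to the peaks that pass.
#' @export
dynamic_threshold_filter <- function(mag, peaks, cfg) {
  stopifnot(inherits(mag, "magnitude_series"),
            inherits(cfg, "dynamic_threshold_config"))
  if (nrow(peaks) == 0) {
    peaks$aver_d <- numeric(0)
    peaks$dynamic_ok <- logical(0)
    return(peaks)
  }
  n <- length(mag$acc)
  half <- cfg$win_size %/% 2L
  aver <- vapply(peaks$index, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    w <- mag$acc[lo:hi]
    (max(w) + min(w)) / 2
  }, numeric(1))
  peaks$aver_d <- aver
  peaks$dynamic_ok <- (peaks$amplitude - aver) >= cfg$th_d
  peaks[peaks$dynamic_ok, , drop = FALSE]
}

#' Vibration-elimination filter
#'
#' Shaking without stepping (hand movement, pocket insertion, vehicle
#' vibration) makes the magnitude fluctuate around 1 g. Each peak's
#' vibration score is its amplitude minus gravity, `Vib_Eli = Acc - 1` (g
#' units); peaks with `Vib_Eli < th_vib` are discarded.
#'
#' @param peaks Peak data frame (needs an `amplitude` column, g units).
#' @param th_vib State-specific threshold in g.
#' @return `peaks` with added `vib_eli` and `vibration_ok` columns,
#'   restricted to the peaks that pass.
#' @export
vibration_filter <- function(peaks, th_vib) {
  if (th_vib <= 0) stop("th_vib must be positive", call. = FALSE)
  peaks$vib_eli <- peaks$amplitude - 1.0
  peaks$vibration_ok <- peaks$vib_eli >= th_vib
  peaks[peaks$vibration_ok, , drop = FALSE]
}

#' State-adaptive peak detection
#'
#' Applies the four Phase-3 constraints in order: candidate peaks under the
#' state's minimal peak distance, minimal peak prominence (evaluated in a
#' `win_size` window centered on each peak), dynamic mid-range thresholding,
#' and vibration elimination. Every filter only removes peaks, so the
#' surviving count is monotone non-increasing in each threshold.
#'
#' @param mag A filtered `magnitude_series`.
#' @param profile A [profile_for()] bundle for the segment's walking state.
#' @param cfg Optional [dynamic_threshold_config()]; defaults to
#'   `th_d = 0.15` with the profile's `win_size`.
#' @param keep_all If `TRUE`, return every candidate with its per-filter
#'   logical flags (`prominence_ok`, `dynamic_ok`, `vibration_ok`) instead
#'   of only the survivors — useful for debugging dumps.
#' @return Peak data frame with columns `index`, `time`, `amplitude`,
#'   `prominence`, `aver_d`, `vib_eli`, `state` and the filter flags; the
#'   survivors have all flags `TRUE`.
#' @export
detect_peaks <- function(mag, profile, cfg = NULL, keep_all = FALSE) {
  stopifnot(inherits(mag, "magnitude_series"),
            inherits(profile, "state_profile"))
  if (is.null(cfg)) cfg <- dynamic_threshold_config(win_size = profile$win_size)
  cands <- candidate_peaks(mag, profile$d)
  half <- profile$win_size %/% 2L
  n <- length(mag$acc)
  cands$prominence <- vapply(cands$index, function(i) {
    peak_prominence(mag, i, c(max(1L, i - half), min(n, i + half)))
  }, numeric(1))
  cands$prominence_ok <- cands$prominence >= profile$H

  scored <- dynamic_threshold_filter(
    mag, cands[cands$prominence_ok, , drop = FALSE], cfg)
  scored <- vibration_filter(scored, profile$th_vib)
  scored$state <- rep(profile$state, nrow(scored))

  if (!keep_all) {
    rownames(scored) <- NULL
    return(scored)
  }
  # annotate the full candidate table with every flag for the debug dump
  half <- cfg$win_size %/% 2L
  cands$aver_d <- vapply(cands$index, function(i) {
    w <- mag$acc[max(1L, i - half):min(n, i + half)]
    (max(w) + min(w)) / 2
  }, numeric(1))
  cands$dynamic_ok <- (cands$amplitude - cands$aver_d) >= cfg$th_d
  cands$vib_eli <- cands$amplitude - 1.0
  cands$vibration_ok <- cands$vib_eli >= profile$th_vib
  cands$state <- rep(profile$state, nrow(cands))
  rownames(cands) <- NULL
  cands
}
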