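# Independent brute-force oracles and shared fixtures for the test suite.
# The oracles are literal transcriptions of the definitions, kept free of
# any code path they are used to check.

make_mag <- function(acc, fs = 50, filtered = TRUE) {
  magnitude_series(seq(0, by = 1 / fs, length.out = length(acc)), acc, fs,
                   filtered = filtered)
}

# exhaustive candidate-peak scan: every interior index compared against all
# d neighbours on each side (clipped at the ends), then plateau collapse and
# greedy suppression
oracle_candidates <- function(x, d) {
  n <- length(x)
  qual <- integer(0)
  if (n > 2 * d) {
    for (j in 2:(n - 1)) {
      if (all(x[j] >= x[max(1, j - d):(j - 1)]) &&
          all(x[j] >= x[(j + 1):min(n, j + d)]))
        qual <- c(qual, j)
    }
  }
  if (length(qual) > 1) {
    keep <- rep(TRUE, length(qual))
    for (k in 2:length(qual))
      if (qual[k] - qual[k - 1] == 1 && x[qual[k]] == x[qual[k - 1]])
        keep[k] <- FALSE
    qual <- qual[keep]
  }
  accepted <- integer(0)
  for (j in qual[order(-x[qual], qual)]) {
    if (!any(abs(accepted - j) <= d)) accepted <- c(accepted, j)
  }
  sort(accepted)
}

# exhaustive prominence: find the first strictly higher sample on each side
# (or the window edge), take the minimum over each intervening interval,
# subtract the higher of the two minima from the peak
oracle_prominence <- function(x, i, lo = 1, hi = length(x)) {
  h <- x[i]
  left_min <- h
  if (i > lo) {
    rng <- lo:(i - 1)
    higher <- rng[x[rng] > h]
    left_min <- if (length(higher) == 0) min(x[rng])
      else if (max(higher) == i - 1) h
      else min(x[(max(higher) + 1):(i - 1)])
  }
  right_min <- h
  if (i < hi) {
    rng <- (i + 1):hi
    higher <- rng[x[rng] > h]
    right_min <- if (length(higher) == 0) min(x[rng])
      else if (min(higher) == i + 1) h
      else min(x[(i + 1):(min(higher) - 1)])
  }
  h - max(left_min, right_min)
}

# direct per-peak recomputation of the mid-range dynamic threshold
oracle_dynamic_keep <- function(x, i, win_size, th_d) {
  half <- win_size %/% 2
  w <- x[max(1, i - half):min(length(x), i + half)]
  (x[i] - (max(w) + min(w)) / 2) >= th_d
}

# Piecewise-linear ten-peak fixture: seven tall peaks with deep valleys and
# three shallow bumps riding on the shoulders between them. Returns the
# signal plus the sample indices and labels of all ten local maxima.
ten_peak_fixture <- function(ramp = 6) {
  nodes <- c(0.90, 1.35, 1.02, 1.62, 1.44, 1.52, 1.05, 1.38, 1.15, 1.47,
             1.33, 1.40, 1.08, 1.55, 1.35, 1.42, 1.12, 1.70, 1.00, 1.45, 0.95)
  labels <- c(NA, "p0", NA, "p1", NA, "b2", NA, "p3", NA, "p4",
              NA, "b5", NA, "p6", NA, "b7", NA, "p8", NA, "p9", NA)
  x <- numeric(0)
  idx <- integer(length(nodes))
  for (k in seq_along(nodes)) {
    if (k == 1) {
      x <- nodes[1]
      idx[1] <- 1L
    } else {
      seg <- seq(nodes[k - 1], nodes[k], length.out = ramp + 1)[-1]
      x <- c(x, seg)
      idx[k] <- length(x)
    }
  }
  list(acc = x, peak_idx = idx[!is.na(labels)],
       peak_label = labels[!is.na(labels)])
}

# Clean walk with tall wide spurious bumps added on top of k true steps;
# used to reproduce the cascade-elimination failure mode of the
# periodicity+similarity+continuity baseline.
walk_with_spurious <- function(state = "normal", n_steps = 60, seed = 7,
                               spike_steps = c(15, 30, 45), spike_amp = 0.6,
                               fs = 50) {
  g <- generate_walk(walk_spec(state = state, n_steps = n_steps, seed = seed), fs)
  m <- sqrt(g$series$ax^2 + g$series$ay^2 + g$series$az^2)
  t <- g$series$t
  for (k in spike_steps) {
    ctr <- g$truth$step_times[k]
    m <- m + spike_amp * ifelse(abs(t - ctr) <= 0.125,
                                0.5 * (1 + cos(2 * pi * (t - ctr) / 0.25)), 0)
  }
  u <- c(0.6, 0.48, 0.64)  # fixed orientation for re-embedding
  u <- u / sqrt(sum(u^2))
  list(series = accel_series(t, m * u[1], m * u[2], m * u[3], fs = fs,
                             units = "g"),
       truth = g$truth)
}
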