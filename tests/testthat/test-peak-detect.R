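test_that("candidate peaks match hand-worked toy cases", {
  ramp <- make_mag(seq(1, 2, length.out = 50))
  expect_equal(nrow(candidate_peaks(ramp, 3)), 0L)

  toy <- make_mag(c(1, 1.3, 1, 1.2, 1))
  expect_equal(candidate_peaks(toy, 1)$index, c(2L, 4L))
  expect_equal(candidate_peaks(toy, 2)$index, 2L)

  expect_equal(nrow(candidate_peaks(make_mag(c(1, 2, 1)), 5)), 0L)  # too short
  expect_error(candidate_peaks(toy, 0), "d must be")
})

test_that("plateaus keep their first index and ties go to the earlier peak", {
  plateau <- make_mag(c(1, 1, 1.5, 1.5, 1.5, 1, 1))
  expect_equal(candidate_peaks(plateau, 2)$index, 3L)
  twin <- make_mag(c(1, 1.4, 1.2, 1.4, 1, 1))
  expect_equal(candidate_peaks(twin, 2)$index, 2L)
})

test_that("candidate peaks agree with the exhaustive scan on random signals", {
  set.seed(101)
  for (rep in 1:60) {
    x <- 1 + cumsum(stats::rnorm(120, 0, 0.1))
    d <- sample(1:15, 1)
    expect_identical(candidate_peaks(make_mag(x), d)$index,
                     oracle_candidates(x, d))
  }
})

test_that("peak count is non-increasing in the minimal peak distance", {
  g <- generate_walk(walk_spec(n_steps = 40, noise_sd = 0.05, seed = 9), 50)
  filt <- lowpass(magnitude(g$series))
  counts <- vapply(c(5, 14, 20), function(d) nrow(candidate_peaks(filt, d)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("prominence matches hand values and the exhaustive oracle", {
  tri <- make_mag(c(0, 1, 0))
  expect_equal(peak_prominence(tri, 2), 1.0)

  set.seed(202)
  for (rep in 1:40) {
    x <- 1 + cumsum(stats::rnorm(200, 0, 0.1))
    m <- make_mag(x)
    for (i in oracle_candidates(x, 3)) {
      expect_equal(peak_prominence(m, i), oracle_prominence(x, i))
      lo <- max(1, i - 20); hi <- min(200, i + 20)
      expect_equal(peak_prominence(m, i, c(lo, hi)),
                   oracle_prominence(x, i, lo, hi))
    }
  }
})

test_that("shallow shoulder bumps have strictly lower prominence than true peaks", {
  fx <- ten_peak_fixture()
  m <- make_mag(fx$acc)
  prom <- vapply(fx$peak_idx, function(i) peak_prominence(m, i), numeric(1))
  names(prom) <- fx$peak_label
  false_peaks <- prom[c("b2", "b5", "b7")]
  true_peaks <- prom[setdiff(names(prom), c("b2", "b5", "b7"))]
  expect_lt(max(false_peaks), min(true_peaks))
  # the slow-state prominence threshold alone separates them
  expect_true(all(true_peaks >= 0.2) && all(false_peaks < 0.2))
  # a taller false bump can still be less prominent than a shorter true peak
  expect_gt(fx$acc[fx$peak_idx[fx$peak_label == "b2"]],
            fx$acc[fx$peak_idx[fx$peak_label == "p3"]])
  expect_lt(prom[["b2"]], prom[["p3"]])
})

test_that("dynamic thresholding follows the mid-range rule", {
  # symmetric triangle wave: mid-range sits halfway up, margin = height / 2
  half <- 12
  wave <- rep(c(seq(1, 1.4, length.out = half + 1),
                seq(1.4, 1, length.out = half + 1)[-1]), 8)[-1]
  m <- make_mag(wave)
  pk <- candidate_peaks(m, half %/% 2)
  cfg <- dynamic_threshold_config(0.15, 2 * half + 1)
  kept <- dynamic_threshold_filter(m, pk, cfg)
  expect_equal(nrow(kept), nrow(pk))          # margin 0.2 >= 0.15

  wave2 <- 1 + (wave - 1) / 2                 # height 0.2, margin 0.1
  m2 <- make_mag(wave2)
  pk2 <- candidate_peaks(m2, half %/% 2)
  expect_equal(nrow(dynamic_threshold_filter(m2, pk2, cfg)), 0L)

  set.seed(303)
  for (rep in 1:30) {
    x <- 1 + cumsum(stats::rnorm(150, 0, 0.08))
    mm <- make_mag(x)
    pkk <- candidate_peaks(mm, 4)
    out <- dynamic_threshold_filter(mm, pkk, dynamic_threshold_config(0.15, 25))
    want <- vapply(pkk$index, oracle_dynamic_keep, logical(1), x = x,
                   win_size = 25, th_d = 0.15)
    expect_identical(out$index, pkk$index[want])
  }
})

test_that("vibration elimination removes peaks fluctuating around gravity", {
  pk <- data.frame(index = 1:3, time = 1:3,
                   amplitude = c(1.0, 1.09, 1.11))
  out <- vibration_filter(pk, 0.1)
  expect_equal(out$amplitude, 1.11)
  expect_equal(out$vib_eli, 0.11)
  expect_equal(nrow(vibration_filter(pk[1, ], 1e-9)), 0L)

  set.seed(404)
  amps <- 1 + stats::runif(50, -0.1, 0.6)
  pkr <- data.frame(index = 1:50, time = 1:50, amplitude = amps)
  counts <- vapply(c(0.05, 0.1, 0.15, 0.3),
                   function(v) nrow(vibration_filter(pkr, v)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("every filter only removes peaks and the chain is threshold-monotone", {
  g <- generate_walk(walk_spec(n_steps = 40, noise_sd = 0.05, seed = 21), 50)
  filt <- lowpass(magnitude(g$series))
  base <- profile_for("normal", 50)
  n_with <- function(overrides = list(), th_d = 0.15) {
    prof <- profile_for("normal", 50, overrides)
    nrow(detect_peaks(filt, prof, dynamic_threshold_config(th_d, prof$win_size)))
  }
  cands <- candidate_peaks(filt, base$d)
  surv <- detect_peaks(filt, base)
  expect_true(all(surv$index %in% cands$index))

  for (par in list(list(name = "H", vals = c(0.1, 0.25, 0.5)),
                   list(name = "th_vib", vals = c(0.05, 0.1, 0.3)),
                   list(name = "d", vals = c(5, 12, 20)))) {
    counts <- vapply(par$vals, function(v) {
      ov <- stats::setNames(list(v), par$name)
      n_with(ov)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0), label = par$name)
  }
  counts_thd <- vapply(c(0.05, 0.15, 0.4), function(v) n_with(th_d = v),
                       numeric(1))
  expect_true(all(diff(counts_thd) <= 0))
})

test_that("distance, prominence and dynamic stages ignore a constant offset", {
  g <- generate_walk(walk_spec(n_steps = 30, seed = 33), 50)
  filt <- lowpass(magnitude(g$series))
  shifted <- magnitude_series(filt$t, filt$acc + 0.4, filt$fs, filtered = TRUE)
  prof <- profile_for("normal", 50)
  a <- detect_peaks(filt, prof, keep_all = TRUE)
  b <- detect_peaks(shifted, prof, keep_all = TRUE)
  expect_identical(a$index, b$index)
  expect_identical(a$prominence_ok, b$prominence_ok)
  expect_identical(a$dynamic_ok, b$dynamic_ok)
  # only the vibration stage sees the offset
  expect_false(identical(a$vibration_ok, b$vibration_ok))
})

test_that("full detection recovers clean strides and ignores pure vibration", {
  expect_equal(nrow(detect_peaks(make_mag(rep(1.2, 400)),
                                 profile_for("normal", 50))), 0L)

  g <- generate_walk(walk_spec(n_steps = 50, noise_sd = 0, seed = 12), 50)
  filt <- lowpass(magnitude(g$series))
  pk <- detect_peaks(filt, profile_for("normal", 50))
  expect_equal(nrow(pk), 50L)

  v <- generate_false_walk(false_walk_spec("vehicle_vibration", duration = 20,
                                           vib_amp = 0.05, seed = 2), 50)
  fv <- lowpass(magnitude(v$series))
  expect_equal(nrow(detect_peaks(fv, profile_for("normal", 50))), 0L)
})
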