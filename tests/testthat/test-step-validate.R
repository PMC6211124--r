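test_that("periodicity and similarity follow their definitions", {
  expect_equal(periodicity(100, 125, 50), 0.5)
  expect_equal(periodicity(100, 101, 50), 0.02)
  expect_error(periodicity(125, 100, 50), "exceed")

  # on a uniform grid the index formula equals the timestamp difference
  m <- make_mag(rep(1, 200), fs = 50)
  expect_equal(periodicity(10, 60, 50), m$t[60] - m$t[10])

  expect_equal(similarity(1.2, 1.2), 0)
  expect_equal(similarity(1.2, 1.5), -0.3)
  expect_equal(similarity(1.5, 1.2), similarity(1.2, 1.5))
})

fake_peaks <- function(times, amps, fs = 50, state = "normal") {
  data.frame(index = round(times * fs), time = times, amplitude = amps,
             state = state)
}

test_that("an isolated peak starts a bout and counts as one step", {
  pk <- fake_peaks(5, 1.4)
  out <- validate_steps(pk, validation_config(), fs = 50)
  expect_equal(nrow(out), 1L)
  expect_true(is.na(out$interval_prev))
})

test_that("a mid-stride spurious peak is rejected without cascading", {
  times <- seq(1, by = 0.5, length.out = 20)
  amps <- rep(1.35, 20)
  pk <- fake_peaks(times, amps)
  # inject a tall extremum 0.15 s after step 10
  spur <- fake_peaks(times[10] + 0.15, 2.2)
  pk2 <- rbind(pk[1:10, ], spur, pk[11:20, ])
  out <- validate_steps(pk2, validation_config(), fs = 50)
  expect_equal(nrow(out), 20L)
  expect_false(any(out$amplitude > 2))
})

test_that("a high peak on the stride grid fails similarity but not its neighbours", {
  times <- seq(1, by = 0.5, length.out = 20)
  amps <- rep(1.35, 20)
  amps[10] <- 2.0   # replaced by a spurious high extremum
  out <- validate_steps(fake_peaks(times, amps), validation_config(), fs = 50)
  expect_equal(nrow(out), 19L)
  expect_false(any(out$amplitude > 1.5))
})

test_that("aperiodic peak trains confirm only bout starts, periodic ones fully", {
  set.seed(7)
  gaps <- stats::runif(10, 0.9, 2.0)        # all above t_max
  pk <- fake_peaks(cumsum(gaps), rep(1.4, 10))
  out <- validate_steps(pk, validation_config(), fs = 50)
  expect_equal(nrow(out), 10L)               # each is its own bout
  expect_true(all(is.na(out$interval_prev)))

  # 0.2 s gaps: each immediate successor is rejected (< t_min), so the
  # interval to the next surviving candidate reaches 0.4 s and confirms —
  # rejection never cascades and never moves the reference step
  close_gaps <- cumsum(c(1, rep(0.2, 9)))
  out2 <- validate_steps(fake_peaks(close_gaps, rep(1.4, 10)),
                         validation_config(), fs = 50)
  expect_equal(nrow(out2), 5L)
  expect_equal(out2$interval_prev[-1], rep(0.4, 4))
})

test_that("an intermittent pause restarts the bout without losing steps", {
  times <- c(seq(1, by = 0.5, length.out = 10),
             seq(10, by = 0.5, length.out = 10))
  out <- validate_steps(fake_peaks(times, rep(1.35, 20)),
                        validation_config(), fs = 50)
  expect_equal(nrow(out), 20L)
  expect_equal(sum(is.na(out$interval_prev)), 2L)
  ok <- !is.na(out$interval_prev)
  expect_true(all(out$interval_prev[ok] >= 0.35 & out$interval_prev[ok] <= 0.8))
})

test_that("the full pipeline counts a still recording as zero steps", {
  still <- accel_series(ax = rep(0, 500), ay = rep(0, 500), az = rep(1, 500),
                        fs = 50)
  r <- count_steps(still)
  expect_equal(r$n_steps, 0L)
})

test_that("the pipeline recovers a clean walk exactly and labels its state", {
  g <- generate_walk(walk_spec(state = "normal", n_steps = 50, noise_sd = 0,
                               seed = 4), 50)
  r <- count_steps(g$series)
  expect_equal(r$n_steps, 50L)
  expect_equal(sum(r$per_state), 50L)
  # the bulk of the bout is labelled normal; boundary windows diluted by the
  # resting lead-in/out may fall to slow, which uses laxer thresholds
  expect_gte(r$per_state[["normal"]], 45L)
  # every detected step matches one true step within a quarter period
  d <- vapply(r$steps$time,
              function(tt) min(abs(g$truth$step_times - tt)), numeric(1))
  expect_lt(max(d), 0.25 * 0.507)
})

test_that("pipeline output is deterministic for a fixed generator seed", {
  g1 <- generate_walk(walk_spec(n_steps = 20, seed = 5), 50)
  g2 <- generate_walk(walk_spec(n_steps = 20, seed = 5), 50)
  expect_identical(count_steps(g1$series)$steps, count_steps(g2$series)$steps)
})

test_that("error metric reproduces its arithmetic and guards T = 0", {
  expect_equal(evaluate_steps(500, 500)$error_pct, 0)
  r <- evaluate_steps(499.2, 500)
  expect_equal(r$error_pct, 0.16, tolerance = 1e-9)
  expect_equal(r$accuracy_pct, 99.84, tolerance = 1e-9)
  r2 <- evaluate_steps(339, 346)
  expect_equal(round(r2$accuracy_pct, 2), 97.98)
  expect_error(evaluate_steps(10, 0), "positive")
})

test_that("yaml configuration overrides reach the pipeline", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("cutoff: 2.5", "th_d: 0.2",
               "classifier:", "  M1: 1.2", "  M2: 1.3",
               "validation:", "  t_min: 0.4", "  t_max: 0.7",
               "states:", "  normal:", "    d: 10"), f)
  cfg <- read_config(f)
  expect_equal(cfg$cutoff, 2.5)
  expect_equal(cfg$th_d, 0.2)
  expect_equal(cfg$classifier$M1, 1.2)
  expect_equal(cfg$validation$t_max, 0.7)
  expect_equal(cfg$profile_overrides$normal$d, 10)
})
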