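test_that("triggered averages: baseline subtraction and window statistics", {
  fs <- 30
  # constant trace -> identically zero response
  r <- triggered_average(rep(5, 3000), c(20, 40, 60), fs)
  expect_equal(max(abs(r$mean)), 0)
  expect_equal(r$n_trials, 3)
  # injected boxcar of amplitude 10 recovered within SG distortion < 2%
  tr <- rep(0, 3000)
  for (on in c(20, 50)) {
    idx <- round(on * fs):round((on + 4) * fs)
    tr[idx] <- 10
  }
  r2 <- triggered_average(tr, c(20, 50), fs, windows = list(w = c(1, 3)))
  expect_equal(r2$window_stats$mean, 10, tolerance = 0.02 * 10)
  # additive constants do not change the response
  r3 <- triggered_average(tr + 100, c(20, 50), fs, windows = list(w = c(1, 3)))
  expect_equal(r3$mean, r2$mean, tolerance = 1e-9)
  # events outside the trace are dropped and counted
  r4 <- triggered_average(tr, c(20, 50, 99.9), fs)
  expect_equal(r4$n_dropped, 1)
  expect_error(triggered_average(tr, 1e5, fs), "usable")
})

test_that("through-origin slope estimator", {
  x <- c(1, 2, 3, 4)
  expect_equal(neurovascular_slope(x, 2 * x), 2)
  # slope is invariant to trial order
  o <- c(3, 1, 4, 2)
  expect_equal(neurovascular_slope(x[o], (2 * x)[o]), 2)
  # orthogonal noise: slope near zero within the null bound
  set.seed(14)
  n <- 400
  a <- rnorm(n); b <- rnorm(n)
  expect_lt(abs(neurovascular_slope(a, b)), 4 / sqrt(n))
  # y = 3x + noise is unbiased
  sl <- replicate(50, {
    x <- rnorm(100); neurovascular_slope(x, 3 * x + rnorm(100))
  })
  expect_equal(mean(sl), 3, tolerance = 3 * stats::sd(sl) / sqrt(50) + 0.02)
  expect_warning(out <- neurovascular_slope(rep(0, 5), 1:5), "undefined")
  expect_true(is.na(out))
})

test_that("state summaries integrate the segmentation and filtering rules", {
  fs <- 30
  # NREM offset +24 in the generator appears as the NREM state mean
  p <- gen_params(seed = 5, vasomotion_sigma = 0, stim_times = no_stim(),
                  hrf_true = list(amplitude = 0, t_peak = 1, shape = 3))
  set.seed(5)
  st <- simulate_state_sequence(p, 300, init = "stationary")
  h <- synthesize_hemodynamics(matrix(1, 300 * 150, 2), st, p)
  lab <- segment_periods(st)
  ss <- state_summaries(h$dHbT[, 1], fs, lab)
  if ("NREM" %in% ss$state) {
    expect_equal(ss$value[ss$state == "NREM" & ss$metric == "mean"], 24,
                 tolerance = 0.15 * 24)
  }
  # zero-signal session: all summaries zero
  lab0 <- segment_periods(all_awake(60))
  ss0 <- state_summaries(rep(0, 60 * 150), fs, lab0)
  expect_true(all(abs(ss0$value) < 1e-12))
  # resting variance matches the generator variance on long rest events
  set.seed(16)
  p2 <- gen_params(vasomotion_sigma = 6.4,
                   hrf_true = list(amplitude = 0, t_peak = 1, shape = 3))
  h2 <- synthesize_hemodynamics(matrix(1, 600 * 150, 2), all_awake(600), p2)
  lab2 <- segment_periods(all_awake(600))
  ss2 <- state_summaries(h2$dHbT[, 1], fs, lab2)
  v <- ss2$value[ss2$metric == "variance"]
  expect_equal(v, 6.4^2, tolerance = 0.2 * 6.4^2)
})

test_that("bilateral comparison recovers shared-drive structure", {
  fs <- 30
  ev <- data.frame(onset_s = seq(0, 540, by = 60), duration_s = 50)
  # identical traces: r = 1 and coherence 1
  set.seed(17)
  x <- nvcoupling:::conv_causal(rnorm(600 * fs), rep(1 / 10, 10), 1)
  bc <- bilateral_comparison(x, x, fs, ev, coh_band = c(0.1, 0.5))
  expect_equal(bc$pearson_r, 1, tolerance = 1e-9)
  expect_equal(bc$coherence, 1, tolerance = 1e-9)
  # generator with shared fraction 0.8: r ~ 0.8
  p8 <- gen_params(vasomotion_sigma = 6, bilateral_shared_fraction = 0.8,
                   hrf_true = list(amplitude = 0, t_peak = 1, shape = 3))
  set.seed(18)
  h8 <- synthesize_hemodynamics(matrix(1, 600 * fs, 2), all_awake(120), p8)
  bc8 <- bilateral_comparison(h8$dHbT[, 1], h8$dHbT[, 2], fs, ev)
  expect_equal(bc8$pearson_r, 0.8, tolerance = 0.1 * 0.8)
  # independent hemispheres: r near zero
  set.seed(19)
  a <- lowpass(rnorm(600 * fs), fs, 1)
  b <- lowpass(rnorm(600 * fs), fs, 1)
  bc0 <- bilateral_comparison(a, b, fs, ev)
  expect_lt(abs(bc0$pearson_r), 0.2)
  expect_error(bilateral_comparison(a, b[1:10], fs, ev), "equal length")
})

test_that("transition deltas measure the pre/post window difference", {
  fs <- 30
  trans <- data.frame(time_s = 100, from = "Awake", to = "NREM")
  # step of +20 at the transition -> delta 20
  x <- c(rep(0, 100 * fs), rep(20, 100 * fs))
  td <- transition_delta(x, fs, trans)
  expect_equal(td$delta, 20, tolerance = 0.01 * 20)
  # linear ramp of slope m crossing zero at the transition -> delta 40*m
  m <- 0.3
  t <- (seq_len(200 * fs) - 1) / fs
  td2 <- transition_delta(m * (t - 100), fs, trans)
  expect_equal(td2$delta, 40 * m, tolerance = 0.02 * 40 * m)
  # no-change trace -> 0
  td3 <- transition_delta(rep(7, 200 * fs), fs, trans)
  expect_equal(td3$delta, 0, tolerance = 1e-9)
  # truncated windows are dropped
  td4 <- transition_delta(x, fs, data.frame(time_s = 10, from = "a", to = "b"))
  expect_equal(nrow(td4), 0)
})

test_that("locomotion onsets require preceding quiescence", {
  fs <- 30
  f <- rep(0, 120 * fs)
  for (on in c(10, 12, 40)) f[round(on * fs):round((on + 1) * fs)] <- 5
  f <- f + rnorm(length(f), 0, 0.01)
  on <- locomotion_onsets(f, fs)
  expect_equal(length(on), 2)          # the 12 s bout is within 5 s of 10 s
  expect_equal(on, c(10, 40), tolerance = 0.2)
})
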