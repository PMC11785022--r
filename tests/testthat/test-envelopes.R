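test_that("band power envelope follows the mean-square of in-band signals", {
  fs <- 1000
  t <- seq(0, 30, by = 1 / fs)
  # DC input has no 30-100 Hz content
  env0 <- band_power_envelope(rep(1, length(t)), fs, c(30, 100))
  expect_lt(mean(env0$values), 1e-6)
  # 50 Hz sinusoid of amplitude a -> steady-state power a^2/2
  for (a in c(1, 3)) {
    env <- band_power_envelope(a * sin(2 * pi * 50 * t), fs, c(30, 100))
    mid <- seq(round(0.2 * length(env$values)), round(0.8 * length(env$values)))
    expect_equal(mean(env$values[mid]), a^2 / 2, tolerance = 0.05 * a^2 / 2)
  }
  expect_error(band_power_envelope(rnorm(1000), 100, c(30, 100)), "Nyquist")
})

test_that("white-noise envelope matches the band's share of total variance", {
  set.seed(3)
  fs <- 1000
  x <- rnorm(60 * fs)
  env <- band_power_envelope(x, fs, c(30, 100))
  mid <- seq(100, length(env$values) - 100)
  # exact oracle: the variance actually passed by the zero-phase bandpass
  expect_equal(mean(env$values[mid]), stats::var(bandpass(x, fs, c(30, 100))),
               tolerance = 0.1 * 0.12)
  # and the ideal band fraction up to the |H|^4 effective-bandwidth loss
  ideal <- (100 - 30) / (fs / 2)
  expect_gt(mean(env$values[mid]), 0.6 * ideal)
  expect_lt(mean(env$values[mid]), 1.1 * ideal)
})

test_that("EMG envelope is a log power measure", {
  set.seed(4)
  fs <- 1000
  x <- rnorm(20 * fs)
  e1 <- suppressWarnings(emg_envelope(x, fs))
  e10 <- suppressWarnings(emg_envelope(10 * x, fs))
  mid <- seq(60, length(e1) - 60)
  # scaling by 10 shifts log10 power by +2
  expect_equal(mean(e10[mid] - e1[mid]), 2, tolerance = 0.01)
  # zero signal hits the floor, not -Inf
  e0 <- suppressWarnings(emg_envelope(rep(0, 20 * fs), fs))
  expect_true(all(is.finite(e0)))
  expect_equal(max(e0), log10(1e-12), tolerance = 1e-6)
  expect_warning(emg_envelope(x, fs), "Nyquist")
})

test_that("cross-correlation conventions: normalization, lag sign, null", {
  set.seed(8)
  fs <- 30
  x <- lowpass(rnorm(3000), fs, 1)
  auto <- cross_correlation(x, x, fs, max_lag_s = 5, f_cut = NULL)
  expect_equal(max(auto$r), 1, tolerance = 1e-9)
  expect_equal(auto$lags_s[which.max(auto$r)], 0)
  # y delayed by 1 s peaks at +1 s (y follows x)
  y <- c(rep(0, fs), x[1:(length(x) - fs)])
  cc <- cross_correlation(x, y, fs, max_lag_s = 5, f_cut = NULL)
  expect_equal(cc$lags_s[which.max(cc$r)], 1)
  expect_true(all(abs(cc$r) <= 1))
  # independent noises stay below the null bound
  n <- 1e4
  a <- rnorm(n); b <- rnorm(n)
  cc0 <- cross_correlation(a, b, 100, max_lag_s = 0.2, f_cut = NULL)
  expect_lt(max(abs(cc0$r)), 4 / sqrt(n))
  expect_error(cross_correlation(a, b, 100, max_lag_s = 200), "lag")
})

test_that("heart-rate estimation finds in-band spectral peaks", {
  fs <- 30
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- 1 + 0.01 * sin(2 * pi * 8 * t)
  hr <- heart_rate_estimate(x, fs)
  expect_true(all(abs(hr - 8) < 0.2))
  # vasomotion-only trace has no in-band peak
  set.seed(2)
  v <- 1 + 0.02 * lowpass(rnorm(length(t)), fs, 0.5)
  expect_true(all(is.na(heart_rate_estimate(v, fs))))
  # chirp 6 -> 10 Hz gives monotone estimates
  f_inst <- seq(6, 10, length.out = length(t))
  chirp <- 1 + 0.01 * sin(2 * pi * cumsum(f_inst) / fs)
  hr3 <- heart_rate_estimate(chirp, fs)
  expect_true(all(diff(hr3) > 0))
  expect_error(heart_rate_estimate(x, 20), "sampling")
})
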