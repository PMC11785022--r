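test_that("state sequences follow the Markov chain", {
  # absorbing (identity) chain stays in the initial state
  p_abs <- gen_params(state_transition_matrix = diag(3))
  set.seed(1)
  st <- simulate_state_sequence(p_abs, 200, init = "Awake")
  expect_true(all(st == "Awake"))
  # forbidden Awake -> REM transition never occurs
  p <- gen_params()
  set.seed(2)
  st2 <- as.integer(simulate_state_sequence(p, 1e5, init = "stationary"))
  pairs <- cbind(st2[-length(st2)], st2[-1])
  expect_equal(sum(pairs[, 1] == 1 & pairs[, 2] == 3), 0)
  # ergodic occupancy matches the stationary eigenvector within 2%
  pi_true <- nvcoupling:::stationary_distribution(p$state_transition_matrix)
  occ <- tabulate(st2, 3) / length(st2)
  expect_true(all(abs(occ - pi_true) < 0.02))
  # invalid matrices are rejected
  bad <- matrix(1 / 3, 3, 3); bad[1, ] <- c(0.5, 0.4, 0.2)
  expect_error(gen_params(state_transition_matrix = bad), "stochastic")
  bad2 <- matrix(c(0.8, 0.1, 0.1, 0.1, 0.8, 0.1, 0.1, 0.1, 0.8), 3, 3,
                 byrow = TRUE)
  expect_error(gen_params(state_transition_matrix = bad2), "REM")
})

test_that("synthetic neural band powers follow the stated state profile", {
  set.seed(3)
  # gamma power 2x between two parameter sets -> measured variance ratio ~2
  bp <- gen_params()$band_power_by_state
  bp["gamma", "Awake"] <- 2; bp["gamma", "NREM"] <- 1
  p <- gen_params(band_power_by_state = bp)
  awake <- all_awake(24)
  nrem <- factor(rep("NREM", 24), levels = levels(awake))
  na <- synthesize_neural(awake, p)
  nn <- synthesize_neural(nrem, p)
  vr <- function(x) {
    est <- multitaper_spectrum(resample_trace(x, 1000, 250), 250, nw = 5, k = 9)
    band_power(est, c(30, 100))
  }
  expect_equal(vr(na$lfp_cortexL) / vr(nn$lfp_cortexL), 2, tolerance = 0.1 * 2)
  # EMG variance strictly greater in NREM than REM (atonia)
  rem <- factor(rep("REM", 24), levels = levels(awake))
  nr <- synthesize_neural(rem, p)
  expect_gt(stats::var(nn$emg), stats::var(nr$emg))
  # zero power in all bands -> all-zero traces
  p0 <- gen_params(band_power_by_state = bp * 0,
                   emg_power_by_state = c(Awake = 0, NREM = 0, REM = 0))
  n0 <- synthesize_neural(awake, p0)
  expect_true(all(n0$lfp_cortexL == 0) && all(n0$emg == 0))
  expect_error(synthesize_neural(factor(character()), p), "non-empty")
})

test_that("hemodynamics: conservation, undershoot, vasomotion, bilaterality", {
  st <- all_awake(120)
  n <- 120 * 5 * 30
  ev <- data.frame(onset_s = 100, type = "brief", duration_s = 0.1, side = "L")
  # undershoot_gain = 0: noiseless post-stimulus window mean >= 0
  p0 <- gen_params(vasomotion_sigma = 0, undershoot_gain = 0,
                   hrf_true = list(amplitude = 0, t_peak = 1, shape = 3))
  h0 <- synthesize_hemodynamics(matrix(1, n, 2), st, p0, ev)
  r0 <- triggered_average(h0$dHbT[, 1], 100, 30, windows = list(u = c(2, 4)))
  expect_gte(r0$window_stats$mean, 0)
  # gain 1 drives the same window negative
  p1 <- gen_params(vasomotion_sigma = 0,
                   hrf_true = list(amplitude = 0, t_peak = 1, shape = 3))
  h1 <- synthesize_hemodynamics(matrix(1, n, 2), st, p1, ev)
  r1 <- triggered_average(h1$dHbT[, 1], 100, 30, windows = list(u = c(2, 4)))
  expect_lt(r1$window_stats$mean, 0)
  # conservation at machine precision
  expect_equal(h1$dHbT, h1$dHbO + h1$dHbR, tolerance = 1e-12)
  # vasomotion SD calibration: sigma = 6 -> resting SD ~6 within 10%
  set.seed(4)
  p6 <- gen_params(vasomotion_sigma = 6,
                   hrf_true = list(amplitude = 0, t_peak = 1, shape = 3))
  h6 <- synthesize_hemodynamics(matrix(1, n, 2), st, p6)
  expect_equal(stats::sd(h6$dHbT[, 1]), 6, tolerance = 0.6)
  # shared fraction 1 with a common envelope: perfect bilateral coherence
  set.seed(4)
  pf <- gen_params(vasomotion_sigma = 6, bilateral_shared_fraction = 1,
                   hrf_true = list(amplitude = 0, t_peak = 1, shape = 3))
  hf <- synthesize_hemodynamics(matrix(1, n, 2), st, pf)
  co <- multitaper_coherence(hf$dHbT[, 1], hf$dHbT[, 2], 30)
  expect_equal(min(co$values), 1, tolerance = 1e-9)
  # shared fraction ~ bilateral Pearson r
  set.seed(5)
  p8 <- gen_params(vasomotion_sigma = 6, bilateral_shared_fraction = 0.8,
                   hrf_true = list(amplitude = 0, t_peak = 1, shape = 3))
  h8 <- synthesize_hemodynamics(matrix(1, n, 2), st, p8)
  expect_equal(stats::cor(h8$dHbT[, 1], h8$dHbT[, 2]), 0.8, tolerance = 0.08)
  # monotonicity: larger vasomotion_sigma -> strictly larger resting variance
  vars <- vapply(c(2, 4, 8), function(sg) {
    set.seed(11)
    p <- gen_params(vasomotion_sigma = sg,
                    hrf_true = list(amplitude = 0, t_peak = 1, shape = 3))
    stats::var(synthesize_hemodynamics(matrix(1, n, 2), st, p)$dHbT[, 1])
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
  expect_error(
    synthesize_hemodynamics(matrix(1, 100, 2), all_awake(100), gen_params()),
    "duration")
})

test_that("state offsets appear as state means", {
  p <- gen_params(seed = 5, vasomotion_sigma = 0, stim_times = no_stim(),
                  hrf_true = list(amplitude = 0, t_peak = 1, shape = 3))
  set.seed(5)
  st <- simulate_state_sequence(p, 300, init = "Awake")
  h <- synthesize_hemodynamics(matrix(1, 300 * 150, 2), st, p)
  nrem_idx <- rep(st == "NREM", each = 150)
  # interior of long NREM runs sits at the +24 uM offset
  if (sum(nrem_idx) > 3000) {
    expect_equal(stats::median(h$dHbT[nrem_idx, 1]), 24, tolerance = 2)
  }
  expect_equal(mean(h$dHbT[rep(st == "Awake", each = 150), 1]), 0,
               tolerance = 3)
})

test_that("sessions are bit-identical under a fixed seed", {
  s1 <- simulate_session(gen_params(seed = 42), duration_s = 300)
  s2 <- simulate_session(gen_params(seed = 42), duration_s = 300)
  expect_identical(s1$channels, s2$channels)
  expect_identical(s1$truth$dHbT, s2$truth$dHbT)
  s3 <- simulate_session(gen_params(seed = 43), duration_s = 300)
  expect_false(identical(s1$channels$lfp_cortexL, s3$channels$lfp_cortexL))
})

test_that("forward render inverts exactly without pulsation", {
  p <- gen_params(seed = 7, heart_pulse_amp = 0)
  ses <- simulate_session(p, duration_s = 300)
  const <- spectroscopy_constants()
  for (hemi in 1:2) {
    I <- cbind(ses$channels[[paste0("refl_480_", c("L", "R")[hemi])]],
               ses$channels[[paste0("refl_530_", c("L", "R")[hemi])]],
               ses$channels[[paste0("refl_630_", c("L", "R")[hemi])]])
    hb <- invert_beer_lambert(delta_absorbance(I, rep(1, 3)), const)
    expect_equal(hb$dHbT, ses$truth$dHbT[, hemi], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # zero concentrations -> reflectance identically I0
  I00 <- forward_beer_lambert(rep(0, 10), rep(0, 10), const, I0 = c(2, 3, 4))
  expect_equal(I00, matrix(rep(c(2, 3, 4), each = 10), 10, 3))
  # fluorescence correction recovers the true calcium signal
  g <- ses$channels$refl_530_L
  base <- which(abs(ses$truth$dff_true[, 1]) < 0.02)
  dff <- correct_fluorescence(ses$channels$fluor_L, g, 1,
                              baseline_idx = seq_along(g))
  expect_gt(stats::cor(dff, ses$truth$dff_true[, 1]), 0.999)
})

test_that("rendered vessel frames measure back to the true diameter", {
  set.seed(8)
  frames <- render_vessel_frames(c(30, 34, 38), img_size = 80,
                                 blur_px = 0.5, noise_sd = 0)
  d <- measure_vessel_stack(frames, register = FALSE)
  expect_equal(as.numeric(d), c(30, 34, 38), tolerance = 0.05 * 38)
})
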