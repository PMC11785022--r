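test_that("FWHM diameter: pulses, Gaussians, half-height definition", {
  # rectangular pulse of width 20 on zero background
  prof <- rep(0, 100); prof[41:60] <- 1
  expect_equal(fwhm_diameter(prof), 20, tolerance = 0.05)
  # Gaussian profiles: FWHM = 2*sqrt(2*log(2))*sigma
  x <- 1:201
  for (sigma in c(3, 4, 6)) {
    prof <- exp(-(x - 101)^2 / (2 * sigma^2))
    expect_equal(fwhm_diameter(prof), 2 * sqrt(2 * log(2)) * sigma,
                 tolerance = 0.02 * 2 * sqrt(2 * log(2)) * sigma)
  }
  # half-height uses background + (peak - background)/2
  prof <- rep(100, 80)
  prof[31:50] <- 300
  prof[c(30, 51)] <- 200  # exact crossings at intensity 200
  d <- fwhm_diameter(prof)
  expect_equal(d, 21, tolerance = 1)
  # pixel size scaling
  expect_equal(fwhm_diameter(prof, pixel_size_um = 2), 2 * d)
  # flat profile: no crossing -> NA with warning
  expect_warning(out <- fwhm_diameter(c(1, 1, 1, 1, 1, 1)), "invalid")
  expect_true(is.na(out))
})

test_that("TiRS recovers disc and ellipse diameters", {
  for (r in c(10, 15, 20)) {
    d <- tirs_diameter(mk_shape(round(3.3 * r), r))
    expect_equal(d, 2 * r, tolerance = 0.05 * 2 * r)
  }
  # rotation invariance: same disc rotated 45 degrees
  d0 <- tirs_diameter(mk_shape(66, 20))
  d45 <- tirs_diameter(mk_shape(66, 20, rot = pi / 4))
  expect_equal(d0, d45, tolerance = 1e-9)
  # ellipse 40x20 axes: equivalent diameter 2*sqrt(ab)
  de <- tirs_diameter(mk_shape(96, 20, 10, rot = pi / 6))
  expect_equal(de, 2 * sqrt(20 * 10), tolerance = 0.07 * 2 * sqrt(200))
  expect_error(tirs_diameter(mk_shape(40, 10) - 2), "non-negative")
})

test_that("TiRS is monotone in disc radius", {
  ds <- vapply(c(8, 11, 14, 18, 22), function(r)
    tirs_diameter(mk_shape(80, r)), numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("FWHM of the central cross-section profile agrees with TiRS", {
  img <- mk_shape(66, 20)
  d_tirs <- tirs_diameter(img)
  d_fwhm <- fwhm_diameter(img[33, ])
  expect_lt(abs(d_tirs - d_fwhm) / d_tirs, 0.10)
})

test_that("rigid registration recovers known shifts", {
  set.seed(12)
  base <- mk_shape(48, 12, blur = 1)
  # majority of frames unshifted so the median frame is the true reference
  shifts <- rbind(c(0, 0), c(0, 0), c(0, 0), c(3, -2), c(-4, 5))
  frames <- array(0, c(48, 48, nrow(shifts)))
  for (i in seq_len(nrow(shifts))) {
    frames[, , i] <- nvcoupling:::shift_image(base, shifts[i, ]) +
      matrix(rnorm(48 * 48, 0, 0.02), 48, 48)
  }
  reg <- register_frames(frames)
  expect_equal(reg$shifts, -shifts, ignore_attr = TRUE)
})

test_that("measured diameter on rendered vessels stays within 5% at SNR >= 5", {
  set.seed(13)
  frames <- render_vessel_frames(rep(30, 6), img_size = 72, blur_px = 0.5,
                                 noise_sd = 0.2)  # SNR = 5
  d <- measure_vessel_stack(frames, register = FALSE)
  expect_equal(attr(d, "n_invalid"), 0)
  expect_lt(abs(mean(d) - 30) / 30, 0.05)
})

test_that("diameter trace summaries", {
  fs <- 5
  # constant diameter: zero percent change and zero variance
  d <- rep(20, 200)
  s <- summarize_diameter(d, fs, data.frame(onset_s = 0, duration_s = 40))
  expect_equal(s$percent_change, rep(0, 200))
  expect_equal(s$resting_variance, 0)
  # sinusoidal percent change of amplitude a -> variance a^2/2
  a <- 8
  t <- seq(0, 199) / fs
  d2 <- 20 * (1 + a / 100 * sin(2 * pi * 0.25 * t))
  s2 <- summarize_diameter(d2, fs, data.frame(onset_s = 0, duration_s = 40),
                           baseline_idx = seq_along(d2))
  expect_equal(s2$resting_variance, a^2 / 2, tolerance = 0.08 * a^2 / 2)
  # isoflurane-like dilation: 23 um baseline stepping to 37.5 um is ~ +63%
  d3 <- c(rep(23, 100), rep(37.5, 100))
  s3 <- summarize_diameter(d3, fs, baseline_idx = 1:100)
  expect_equal(mean(s3$percent_change[101:200]), 100 * (37.5 - 23) / 23,
               tolerance = 0.01)
  # short rest events are excluded; none left -> NA variance
  s4 <- summarize_diameter(d, fs, data.frame(onset_s = 0, duration_s = 5))
  expect_true(is.na(s4$resting_variance))
})
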