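# Power envelopes, cross-correlation, and heart-rate extraction.

#' Canonical frequency bands (Hz)
#'
#' Delta 1-4, theta 4-10, beta 13-30, gamma 30-100 Hz.
#' @export
nvc_bands <- list(delta = c(1, 4), theta = c(4, 10),
                  beta = c(13, 30), gamma = c(30, 100))

#' Band-limited power envelope at 30 Hz
#'
#' Isolates a frequency band with a zero-phase 3rd-order Butterworth bandpass,
#' squares, lowpass filters below 1 Hz (zero-phase), and resamples to 30 Hz.
#' This is the standard neural drive signal (e.g. gamma-band power).
#'
#' @param x broadband trace.
#' @param fs sampling rate, Hz; must exceed twice the upper band edge.
#' @param band length-2 band, Hz.
#' @param fs_out output rate, Hz (default 30).
#' @return object of class `band_envelope`: list with `values` (a.u., >= 0
#'   up to filter ripple), `band`, `fs`.
#' @export
band_power_envelope <- function(x, fs, band, fs_out = 30) {
  if (fs <= 2 * band[2]) stop("band extends beyond Nyquist")
  p <- bandpass(x, fs, band, order = 3)^2
  p <- lowpass(p, fs, 1, order = 3)
  v <- resample_trace(p, fs, fs_out)
  structure(list(values = v, band = band, fs = fs_out),
            class = "band_envelope")
}

#' EMG log-power envelope at 30 Hz
#'
#' Bandpass 300-3000 Hz (truncated at Nyquist with a warning when the
#' sampling rate is too low), square, Gaussian smooth (sd 0.5 s), log10 with
#' a floor, resample to 30 Hz.
#'
#' @param x nuchal EMG trace.
#' @param fs sampling rate, Hz.
#' @param band nominal EMG band, Hz (default `c(300, 3000)`).
#' @param floor_power lower bound applied before the log (default 1e-12 a.u.).
#' @param fs_out output rate, Hz (default 30).
#' @return numeric log10-power envelope at `fs_out`.
#' @export
emg_envelope <- function(x, fs, band = c(300, 3000), floor_power = 1e-12,
                         fs_out = 30) {
  hi <- 0.95 * fs / 2
  if (band[2] > hi) {
    warning("EMG band truncated at Nyquist (fs = ", fs, " Hz)", call. = FALSE)
    band[2] <- hi
  }
  if (band[1] >= band[2]) stop("sampling rate too low for the EMG band")
  p <- bandpass(x, fs, band, order = 3)^2
  p <- gaussian_smooth(p, sd_samples = 0.5 * fs)
  p <- log10(pmax(p, floor_power))
  resample_trace(p, fs, fs_out)
}

#' Normalized cross-correlation with bounded lag
#'
#' Both traces are mean-subtracted and zero-phase lowpass filtered below
#' `f_cut` Hz (4th-order Butterworth) before correlation. Normalization is by
#' the zero-lag autocorrelations, so `x` vs `x` peaks at exactly 1. Sign
#' convention: a peak at positive lag means `y` lags (follows) `x`.
#'
#' @param x,y equal-length traces.
#' @param fs sampling rate, Hz.
#' @param max_lag_s maximum lag, seconds (default 5).
#' @param f_cut lowpass corner, Hz (default 1); `NULL` skips filtering.
#' @return list with `lags_s` and `r` (normalized correlation, in `[-1, 1]`).
#' @export
cross_correlation <- function(x, y, fs, max_lag_s = 5, f_cut = 1) {
  if (length(x) != length(y)) stop("traces must have equal length")
  ml <- round(max_lag_s * fs)
  if (ml >= length(x)) stop("max_lag longer than the trace")
  if (!is.null(f_cut)) {
    x <- lowpass(x - mean(x), fs, f_cut, order = 4)
    y <- lowpass(y - mean(y), fs, f_cut, order = 4)
  }
  x <- x - mean(x); y <- y - mean(y)
  cc <- stats::ccf(y, x, lag.max = ml, plot = FALSE, demean = FALSE)
  denom <- sqrt(sum(x^2) * sum(y^2))
  # ccf uses 1/n scaling of the cross-covariance against sd(x)sd(y) with the
  # same n; rescale so lag-0 autocorrelation is exactly 1.
  r <- as.numeric(cc$acf) * (stats::sd(x) * stats::sd(y) * length(x)) / denom
  list(lags_s = as.numeric(cc$lag) / fs, r = pmin(pmax(r, -1), 1))
}

#' Heart-rate estimate per 5-s bin
#'
#' Takes the spectral peak of the isosbestic (530-nm) reflectance within
#' 5-14 Hz for each 5-s bin; bins whose peak does not rise above the local
#' noise floor are returned as `NA`.
#'
#' @param x 530-nm ROI reflectance trace.
#' @param fs sampling rate, Hz (must be at least 28 so the band is resolvable).
#' @param bin_s bin length, seconds (default 5).
#' @param band search band, Hz (default `c(5, 14)`).
#' @param min_prominence required ratio of the in-band peak to the in-band
#'   median power (default 5).
#' @return numeric vector, one rate (Hz) per complete bin, `NA` when missing.
#' @export
heart_rate_estimate <- function(x, fs, bin_s = 5, band = c(5, 14),
                                min_prominence = 5) {
  if (fs < 28) stop("sampling rate too low for heart-rate estimation")
  nbin <- round(bin_s * fs)
  nb <- floor(length(x) / nbin)
  out <- rep(NA_real_, nb)
  nfft <- max(1024L, stats::nextn(nbin, 2))  # zero-pad for a fine peak grid
  for (i in seq_len(nb)) {
    seg <- x[((i - 1) * nbin + 1):(i * nbin)]
    est <- multitaper_spectrum(seg, fs, nw = 2, k = 3, nfft = nfft)
    sel <- est$freqs >= band[1] & est$freqs <= band[2]
    pin <- est$values[sel]
    if (max(pin) > min_prominence * stats::median(pin)) {
      out[i] <- est$freqs[sel][which.max(pin)]
    }
  }
  out
}
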