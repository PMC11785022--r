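# Zero-phase IIR filtering primitives. All user-facing filters are applied
# forward-backward (filtfilt) so that envelopes and evoked responses are not
# delayed relative to the raw traces.

#' Design a digital Butterworth filter
#'
#' Computes transfer-function coefficients for a Butterworth filter via the
#' analog prototype and bilinear transform, matching the usual `butter()`
#' convention: `w` is expressed as a fraction of the Nyquist frequency.
#'
#' @param n filter order (per section; a bandpass of order `n` has `2n` poles).
#' @param w normalized cutoff, scalar for low/high pass or length-2 for
#'   bandpass, in (0, 1) where 1 is Nyquist.
#' @param type one of `"low"`, `"high"`, `"pass"`.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @examples
#' bf <- butter_design(3, 0.2, "low")
#' @export
butter_design <- function(n, w, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (n < 1 || n != round(n)) stop("filter order must be a positive integer")
  if (any(w <= 0) || any(w >= 1)) stop("normalized frequency must lie in (0, 1)")
  if (type == "pass" && length(w) != 2) stop("bandpass requires two corner frequencies")
  if (type != "pass" && length(w) != 1) stop("low/high pass require one corner frequency")
  if (type == "pass" && w[1] >= w[2]) stop("bandpass corners must be increasing")

  # analog Butterworth prototype poles on the unit circle (left half-plane)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))

  warp <- tan(pi * w / 2)  # bilinear prewarp, T = 2
  if (type == "low") {
    p <- warp * p
    z <- complex(0)
    gain <- warp^n
  } else if (type == "high") {
    p <- warp / p
    z <- rep(0 + 0i, n)
    gain <- 1
  } else {
    w0 <- sqrt(prod(warp))
    bw <- warp[2] - warp[1]
    pa <- p * bw / 2
    disc <- sqrt(pa^2 - w0^2)
    p <- c(pa + disc, pa - disc)
    z <- rep(0 + 0i, n)
    gain <- bw^n
  }

  # bilinear transform s -> (z-1)/(z+1)
  pz <- (1 + p) / (1 - p)
  zz <- (1 + z) / (1 - z)
  n_extra <- length(p) - length(z)       # zeros at s = Inf map to z = -1
  zz <- c(zz, rep(-1 + 0i, n_extra))
  gain <- gain * Re(prod(1 - z) / prod(1 - p))

  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(zz)) * gain
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Single-pass IIR filter (direct form I) built on stats::filter for speed.
iir_filter <- function(x, b, a) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  if (nb > 1) {
    v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution", sides = 1)
    v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  } else {
    v <- b * x
  }
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies an IIR filter forward then backward so the net phase response is
#' zero. Edge transients are suppressed by odd-reflection padding.
#'
#' @param x numeric trace.
#' @param b,a transfer-function coefficients from [butter_design()].
#' @param pad padding length in samples; defaults to 3x the filter memory but
#'   should cover a few time constants of the slowest pole (the convenience
#'   wrappers compute this from the corner frequency).
#' @return filtered trace, same length as `x`.
#' @export
filtfilt <- function(x, b, a, pad = NULL) {
  nx <- length(x)
  if (is.null(pad)) pad <- 3 * (max(length(a), length(b)) - 1)
  pad <- max(1L, min(nx - 1L, as.integer(pad)))
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[nx] - x[(nx - 1):(nx - pad)]
  xp <- c(front, x, back)
  y <- iir_filter(xp, b, a)
  y <- rev(iir_filter(rev(y), b, a))
  y[(pad + 1):(pad + nx)]
}

pad_for_corner <- function(fs, f_corner, n) {
  # cover ~6 time constants of a pole near the lowest corner frequency
  max(24L, min(n - 1L, as.integer(ceiling(6 * fs / f_corner))))
}

#' Zero-phase Butterworth lowpass
#'
#' @param x numeric trace.
#' @param fs sampling rate, Hz.
#' @param f_cut corner frequency, Hz.
#' @param order filter order (default 4, the convention used for hemodynamic
#'   lowpass filtering below 1 Hz).
#' @return filtered trace.
#' @export
lowpass <- function(x, fs, f_cut, order = 4) {
  if (f_cut >= fs / 2) stop("corner frequency must be below Nyquist")
  d <- butter_design(order, f_cut / (fs / 2), "low")
  filtfilt(x, d$b, d$a, pad = pad_for_corner(fs, f_cut, length(x)))
}

#' Zero-phase Butterworth bandpass
#'
#' @inheritParams lowpass
#' @param band length-2 vector of corner frequencies, Hz.
#' @param order per-section order (default 3, the convention used for LFP
#'   band isolation).
#' @return filtered trace.
#' @export
bandpass <- function(x, fs, band, order = 3) {
  if (band[2] >= fs / 2) stop("upper band edge must be below Nyquist")
  d <- butter_design(order, band / (fs / 2), "pass")
  filtfilt(x, d$b, d$a, pad = pad_for_corner(fs, band[1], length(x)))
}

#' Anti-aliased resampling onto a uniform grid
#'
#' Band-limits `x` below the target Nyquist with a zero-phase Butterworth
#' lowpass, then linearly interpolates onto the `fs_out` grid. Upsampling uses
#' interpolation only.
#'
#' @param x numeric trace sampled at `fs_in`.
#' @param fs_in,fs_out input and output sampling rates, Hz.
#' @return numeric trace of length `floor(length(x) * fs_out / fs_in)`.
#' @export
resample_trace <- function(x, fs_in, fs_out) {
  n_out <- floor(length(x) * fs_out / fs_in)
  if (fs_out < fs_in) x <- lowpass(x, fs_in, 0.45 * fs_out, order = 4)
  t_in <- (seq_along(x) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with reflection padding, the
#' standard smoother for evoked-response traces.
#'
#' @param x numeric trace.
#' @param order polynomial order (default 3).
#' @param window odd window length in samples (default 17, about 0.57 s at
#'   30 Hz).
#' @return smoothed trace.
#' @export
savitzky_golay <- function(x, order = 3, window = 17) {
  if (window %% 2 == 0) stop("window length must be odd")
  if (order >= window) stop("order must be below window length")
  m <- (window - 1) / 2
  A <- outer(seq(-m, m), 0:order, `^`)
  h <- (A %*% solve(crossprod(A), t(A)))[m + 1, ]
  xp <- c(x[(m + 1):2], x, x[(length(x) - 1):(length(x) - m)])
  as.numeric(stats::filter(xp, rev(h), method = "convolution", sides = 1))[
    (2 * m + 1):(2 * m + length(x))]
}

#' Gaussian kernel smoothing
#'
#' @param x numeric trace.
#' @param sd_samples kernel standard deviation in samples.
#' @return smoothed trace (reflection padding at edges).
#' @export
gaussian_smooth <- function(x, sd_samples) {
  m <- max(1L, ceiling(4 * sd_samples))
  k <- stats::dnorm(seq(-m, m), sd = sd_samples)
  k <- k / sum(k)
  n <- length(x)
  if (m + 1 <= n) {
    xp <- c(x[(m + 1):2], x, x[(n - 1):(n - m)])
  } else {
    xp <- c(rep(x[1], m), x, rep(x[n], m))
  }
  if (length(k) > 64) {
    # FFT convolution for long kernels
    out <- stats::convolve(xp, k, type = "open")
    out[(2 * m + 1):(2 * m + n)]
  } else {
    as.numeric(stats::filter(xp, rev(k), method = "convolution",
                             sides = 1))[(2 * m + 1):(2 * m + n)]
  }
}

#' Linear detrending
#'
#' Removes the least-squares line from a trace (the per-event detrend used
#' before spectral estimation).
#'
#' @param x numeric trace.
#' @return detrended trace.
#' @export
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2) return(x - mean(x))
  t <- seq_len(n)
  stats::residuals(stats::lm.fit(cbind(1, t), x))
}
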