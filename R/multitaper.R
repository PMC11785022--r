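# Multitaper spectral estimation (DPSS tapers), coherence, and spectrograms.
# PSD normalization is one-sided and satisfies Parseval:
#   sum(psd) * df  ~=  var(x)   for detrended stationary input.

.dpss_cache <- new.env(parent = emptyenv())

dpss_tridiag <- function(n, nw, k) {
  # eigenvectors of the classic symmetric tridiagonal commuting matrix
  w <- nw / n
  t <- 0:(n - 1)
  dg <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  od <- t[-1] * (n - t[-1]) / 2
  m <- diag(dg)
  m[cbind(1:(n - 1), 2:n)] <- od
  m[cbind(2:n, 1:(n - 1))] <- od
  e <- eigen(m, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  fix_dpss_sign(v)
}

fix_dpss_sign <- function(v) {
  for (j in seq_len(ncol(v))) {
    s <- sum(v[, j])
    ref <- if (abs(s) > 1e-10) s else v[2, j] - v[1, j]
    if (ref < 0) v[, j] <- -v[, j]
  }
  v
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Returns `k` unit-energy DPSS tapers of length `n` with time-bandwidth
#' product `nw`. For long tapers (`n > 1024`) the tapers are computed exactly
#' at length 1024, interpolated, and re-orthonormalized; the spectral
#' concentration loss of this approximation is negligible for the estimates
#' used here.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers; must satisfy `k <= 2*nw - 1`.
#' @return `n x k` matrix, columns orthonormal.
#' @export
dpss_tapers <- function(n, nw, k) {
  if (k > 2 * nw - 1 + 1e-9) stop("taper count k must not exceed 2*NW - 1")
  if (n < 2 * k) stop("taper length too short for requested taper count")
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  if (n <= 1024) {
    v <- dpss_tridiag(n, nw, k)
  } else {
    n0 <- 1024
    v0 <- dpss_tridiag(n0, nw, k)
    g_in <- seq(0, 1, length.out = n0)
    g_out <- seq(0, 1, length.out = n)
    v <- apply(v0, 2, function(col) stats::spline(g_in, col, xout = g_out)$y)
    v <- fix_dpss_sign(qr.Q(qr(v))) # re-orthonormalize
  }
  v <- sweep(v, 2, sqrt(colSums(v^2)), `/`)
  .dpss_cache[[key]] <- v
  v
}

taper_ffts <- function(x, tapers, nfft) {
  n <- length(x)
  xt <- tapers * x           # n x k
  xt <- rbind(xt, matrix(0, nfft - n, ncol(tapers)))
  stats::mvfft(xt)
}

#' Multitaper power spectrum
#'
#' Averages `k` DPSS-tapered periodograms of a (detrended) trace. One-sided
#' density: `sum(values) * diff(freqs)[1]` approximates the signal variance.
#'
#' @param x numeric trace.
#' @param fs sampling rate, Hz.
#' @param nw time-bandwidth product (default 3).
#' @param k taper count (default `2*nw - 1`).
#' @param detrend remove the best-fit line first (default TRUE).
#' @param nfft FFT length (defaults to the next power of two).
#' @return object of class `spectral_estimate` with `freqs`, `values`,
#'   `kind = "spectrum"`, and taper metadata.
#' @export
multitaper_spectrum <- function(x, fs, nw = 3, k = 2 * nw - 1, detrend = TRUE,
                                nfft = NULL) {
  n <- length(x)
  if (n < 8) stop("trace too short for spectral estimation")
  if (detrend) x <- detrend_linear(x)
  if (is.null(nfft)) nfft <- stats::nextn(n, 2)
  tapers <- dpss_tapers(n, nw, k)
  X <- taper_ffts(x, tapers, nfft)
  psd2 <- rowMeans(Mod(X)^2) / fs
  half <- seq_len(nfft %/% 2 + 1)
  psd <- psd2[half]
  scale2 <- rep(2, length(half)); scale2[1] <- 1
  if (nfft %% 2 == 0) scale2[length(half)] <- 1
  psd <- psd * scale2
  structure(list(freqs = (half - 1) * fs / nfft, values = psd,
                 kind = "spectrum", nw = nw, k = k, fs = fs),
            class = "spectral_estimate")
}

#' Multitaper magnitude coherence
#'
#' Magnitude coherence `|Sxy| / sqrt(Sxx * Syy)` with cross- and auto-spectra
#' averaged over tapers, and over events when `x`/`y` are lists of
#' equal-length segments (taper-pooled, the standard event-averaged
#' estimator).
#'
#' @param x,y traces, or lists of equal-length trace segments (events).
#' @param fs sampling rate, Hz.
#' @param nw time-bandwidth product (default 3).
#' @param k taper count (default `2*nw - 1`).
#' @param detrend remove per-event best-fit lines first (default TRUE).
#' @return `spectral_estimate` with `kind = "coherence"`, values in `[0, 1]`.
#' @export
multitaper_coherence <- function(x, y, fs, nw = 3, k = 2 * nw - 1,
                                 detrend = TRUE) {
  if (!is.list(x)) x <- list(x)
  if (!is.list(y)) y <- list(y)
  if (length(x) != length(y)) stop("x and y must contain the same number of events")
  n <- length(x[[1]])
  if (any(vapply(c(x, y), length, 1L) != n)) {
    stop("all event segments must share one length")
  }
  nfft <- stats::nextn(n, 2)
  tapers <- dpss_tapers(n, nw, k)
  half <- seq_len(nfft %/% 2 + 1)
  sxx <- syy <- numeric(length(half))
  sxy <- complex(length(half))
  for (i in seq_along(x)) {
    xi <- x[[i]]; yi <- y[[i]]
    if (detrend) { xi <- detrend_linear(xi); yi <- detrend_linear(yi) }
    X <- taper_ffts(xi, tapers, nfft)[half, , drop = FALSE]
    Y <- taper_ffts(yi, tapers, nfft)[half, , drop = FALSE]
    sxx <- sxx + rowSums(Mod(X)^2)
    syy <- syy + rowSums(Mod(Y)^2)
    sxy <- sxy + rowSums(X * Conj(Y))
  }
  coh <- Mod(sxy) / sqrt(pmax(sxx * syy, .Machine$double.xmin))
  structure(list(freqs = (half - 1) * fs / nfft, values = pmin(coh, 1),
                 kind = "coherence", nw = nw, k = k * length(x), fs = fs),
            class = "spectral_estimate")
}

#' Multitaper spectrogram
#'
#' Sliding-window multitaper spectrum. Defaults follow the LFP convention:
#' 5-s window, 0.2-s step, time-bandwidth 5 with 9 tapers.
#'
#' @param x numeric trace.
#' @param fs sampling rate, Hz.
#' @param window_s,step_s window and step length, seconds.
#' @param nw,k taper parameters (defaults 5 and 9).
#' @param fpass keep frequencies within this band (default `c(0, fs/2)`).
#' @return `spectral_estimate` with `kind = "spectrogram"`, `values` a
#'   `freq x time` matrix and `times` the window centers (s).
#' @export
multitaper_spectrogram <- function(x, fs, window_s = 5, step_s = 1 / 5,
                                   nw = 5, k = 9, fpass = c(0, fs / 2)) {
  nwin <- round(window_s * fs)
  nstep <- max(1L, round(step_s * fs))
  if (length(x) < nwin) stop("trace shorter than one spectrogram window")
  starts <- seq(1L, length(x) - nwin + 1L, by = nstep)
  nfft <- stats::nextn(nwin, 2)
  tapers <- dpss_tapers(nwin, nw, k)
  half <- seq_len(nfft %/% 2 + 1)
  freqs <- (half - 1) * fs / nfft
  keep <- freqs >= fpass[1] & freqs <= fpass[2]
  vals <- matrix(0, sum(keep), length(starts))
  scale2 <- rep(2, length(half)); scale2[1] <- 1
  if (nfft %% 2 == 0) scale2[length(half)] <- 1
  for (j in seq_along(starts)) {
    seg <- detrend_linear(x[starts[j]:(starts[j] + nwin - 1L)])
    X <- taper_ffts(seg, tapers, nfft)
    psd <- rowMeans(Mod(X[half, , drop = FALSE])^2) / fs * scale2
    vals[, j] <- psd[keep]
  }
  structure(list(freqs = freqs[keep], values = vals, kind = "spectrogram",
                 times = (starts - 1 + nwin / 2) / fs, nw = nw, k = k,
                 fs = fs, window_s = window_s, step_s = step_s),
            class = "spectral_estimate")
}

#' Mean power in a frequency band
#'
#' @param est a `spectral_estimate` (spectrum or coherence).
#' @param band length-2 frequency band, Hz.
#' @return mean of `values` over frequencies inside `band` (for spectra this
#'   is mean density; multiply by bandwidth for integrated power).
#' @export
band_mean <- function(est, band) {
  sel <- est$freqs >= band[1] & est$freqs <= band[2]
  if (!any(sel)) stop("no frequencies inside the requested band")
  mean(est$values[sel])
}

#' Integrated band power
#'
#' @inheritParams band_mean
#' @return integral of the spectral density over `band` (a.u., i.e. the
#'   variance contributed by the band).
#' @export
band_power <- function(est, band) {
  sel <- est$freqs >= band[1] & est$freqs <= band[2]
  if (!any(sel)) stop("no frequencies inside the requested band")
  df <- if (length(est$freqs) > 1) est$freqs[2] - est$freqs[1] else 1
  sum(est$values[sel]) * df
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat("<spectral_estimate>", x$kind, "\n")
  cat("  freqs:", length(x$freqs), "bins,",
      signif(min(x$freqs), 3), "-", signif(max(x$freqs), 3), "Hz\n")
  cat("  tapers: NW =", x$nw, ", K =", x$k, "\n")
  invisible(x)
}
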