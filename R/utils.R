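`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gamma-variate kernel
#'
#' `h(t) = A * (t/t_p)^alpha * exp(alpha * (1 - t/t_p))` for `t >= 0`; the
#' canonical single-lobe hemodynamic impulse response with peak value `A` at
#' time-to-peak `t_p` and shape `alpha`.
#'
#' @param t time, seconds (values < 0 give 0).
#' @param amplitude peak value `A`.
#' @param t_peak time-to-peak, seconds.
#' @param shape shape parameter `alpha` (> 0).
#' @return kernel values.
#' @export
gamma_variate <- function(t, amplitude, t_peak, shape) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- amplitude * (t[pos] / t_peak)^shape *
    exp(shape * (1 - t[pos] / t_peak))
  out
}

# causal convolution of a signal with a sampled kernel, scaled by dt so the
# result approximates the continuous-time integral
conv_causal <- function(x, kernel, dt = 1) {
  n <- length(x)
  full <- stats::convolve(x, rev(kernel), type = "open")
  full[seq_len(n)] * dt
}

# contiguous runs of TRUE as a two-column matrix (start, end), in indices
runs_true <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Per-group sample size for a two-sample t-test (normal approximation)
#'
#' `n = 2 * ((z_{1-alpha/2} + z_{power}) / d)^2`, rounded up; the standard
#' power-analysis formula for a two-sided two-sample comparison at effect
#' size `d` (Cohen's d).
#'
#' @param d standardized effect size.
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.80).
#' @return integer sample size per group.
#' @export
power_sample_size <- function(d, alpha = 0.05, power = 0.80) {
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  ceiling(2 * ((z_a + z_b) / d)^2)
}
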