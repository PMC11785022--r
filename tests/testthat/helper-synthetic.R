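# Shared fixtures built in code. Sessions are cached per test run so several
# test files can reuse the same (deterministic) simulations.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# disc / ellipse / blurred test images for diametry
mk_shape <- function(n, a, b = a, rot = 0, blur = 0, background = 0) {
  xg <- matrix(rep(seq_len(n) - (n + 1) / 2, each = n), n, n)
  yg <- t(xg)
  xr <- xg * cos(rot) + yg * sin(rot)
  yr <- -xg * sin(rot) + yg * cos(rot)
  img <- ((xr / a)^2 + (yr / b)^2 <= 1) * 1.0
  if (blur > 0) {
    k <- stats::dnorm(seq(-ceiling(3 * blur), ceiling(3 * blur)), sd = blur)
    k <- k / sum(k)
    img <- apply(img, 2, function(col)
      as.numeric(stats::filter(col, k, circular = TRUE)))
    img <- t(apply(img, 1, function(row)
      as.numeric(stats::filter(row, k, circular = TRUE))))
  }
  img + background
}

no_stim <- function() {
  data.frame(onset_s = numeric(), type = character(),
             duration_s = numeric(), side = character())
}

all_awake <- function(n_bins) {
  factor(rep("Awake", n_bins), levels = c("Awake", "NREM", "REM"))
}

# a mid-sized default session shared by the sleep/pipeline tests
small_session <- function() {
  cached("small_session", simulate_session(gen_params(seed = 9),
                                           duration_s = 2400))
}

small_features <- function() {
  cached("small_features", extract_features(small_session()))
}
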