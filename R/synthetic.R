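# Synthetic multimodal session generator. Produces arousal-state-structured
# sessions with known ground truth: a Markov state sequence in 5-s bins,
# state-dependent band-limited LFP/EMG, hemodynamics driven by convolving the
# gamma-band power envelope with a gamma-variate kernel plus vasomotion and
# stimulus transients, forward-rendered reflectance with attenuated
# fluorescence, and vessel cross sections with known diameter.

#' Generator parameters
#'
#' The stated world of the synthetic sessions. Defaults emulate a head-fixed
#' mouse during the light phase: long awake bouts interleaved with NREM sleep
#' and briefer REM episodes (REM entered only from NREM), elevated cortical
#' delta power in NREM, elevated hippocampal theta and near-zero EMG power in
#' REM (atonia), resting blood-volume fluctuations (vasomotion, 0.05-0.3 Hz)
#' of ~6.4 uM SD so the resting variance sits near 41 uM^2, NREM/REM blood
#' volume elevations of +24/+75 uM, a sustained-stimulus response of ~18.7 uM
#' (1.5-6.5 s window) with a post-stimulus undershoot bringing the 2-4 s
#' window of the brief-stimulus response to about -2.2 uM at gain 1, and a
#' bilateral shared fraction of 0.8 so resting interhemispheric blood-volume
#' coherence sits near 0.8.
#'
#' @param state_transition_matrix 3x3 row-stochastic matrix of per-5-s-bin
#'   transition probabilities, states ordered Awake, NREM, REM. Awake -> REM
#'   transitions are forbidden.
#' @param band_power_by_state band x state matrix of LFP band variances
#'   (a.u.); rows `delta`, `beta`, `gamma` (cortex) and `theta`
#'   (hippocampus), columns `Awake`, `NREM`, `REM`.
#' @param emg_power_by_state EMG variance per state (a.u.); REM is lowest
#'   (muscle atonia).
#' @param hrf_true list `(amplitude, t_peak, shape)` of the gamma-variate
#'   kernel coupling gamma-band power to blood volume (uM per a.u. * s).
#' @param undershoot_gain unitless scale of the delayed negative
#'   post-stimulus component (1 = control physiology, 0 = no undershoot).
#' @param vasomotion_sigma SD (uM) of the resting 0.05-0.3 Hz blood-volume
#'   fluctuation.
#' @param bilateral_shared_fraction fraction (0-1) of the stochastic
#'   hemodynamic drive common to both hemispheres.
#' @param state_hbt_offset_uM blood-volume elevation per state (uM).
#' @param evoked_amp_uM calibrated mean of the noiseless 1.5-6.5 s response
#'   window to a 5-s stimulus (uM).
#' @param brief_peak_uM calibrated peak of the noiseless positive response
#'   lobe to a brief (0.1 s) stimulus (uM; brief responses are
#'   disproportionately large relative to linear duration scaling).
#' @param undershoot_uM calibrated magnitude of the 2-4 s window mean of the
#'   noiseless brief-stimulus response at gain 1 (uM).
#' @param oxy_ratio evoked oxygenation split: `dHbO = oxy_ratio * dHbT`,
#'   `dHbR = (1 - oxy_ratio) * dHbT` (default 1.3, so dHbR is negative for
#'   positive dHbT).
#' @param heart_rate_by_state pulse frequency per state, Hz.
#' @param heart_pulse_amp relative amplitude of the heart-rate pulsation on
#'   the isosbestic reflectance (default 0.01; 0 disables it for noiseless
#'   round-trip checks).
#' @param baseline_diameter_um resting arteriole diameter, um.
#' @param diameter_percent_per_uM percent diameter change per uM dHbT.
#' @param stim_times data.frame with `onset_s`, `type` (`"brief"`, `"long"`,
#'   `"auditory"`), `duration_s`, `side` (`"L"`/`"R"`), or NULL to
#'   auto-generate puffs every 30-45 s over the first `stim_period_s`.
#' @param stim_period_s duration of the stimulation period at session start
#'   (s; default 3600 like the experimental protocol, truncated to the
#'   session).
#' @param stim_gamma_gain multiplicative gamma-power boost during stimuli.
#' @param fs_neural,fs_optical sampling rates (Hz) of electrophysiology and
#'   optical channels.
#' @param seed integer seed making the session reproducible.
#' @return object of class `gen_params`.
#' @export
gen_params <- function(
    state_transition_matrix = matrix(c(
      0.9920, 0.0080, 0.0000,
      0.0025, 0.9900, 0.0075,
      0.0200, 0.0200, 0.9600), 3, 3, byrow = TRUE,
      dimnames = list(c("Awake", "NREM", "REM"), c("Awake", "NREM", "REM"))),
    band_power_by_state = matrix(c(
      1.0, 4.0, 0.8,    # delta
      1.0, 1.5, 0.8,    # beta
      1.0, 0.7, 1.3,    # gamma
      1.0, 0.8, 3.5),   # theta (hippocampus)
      4, 3, byrow = TRUE,
      dimnames = list(c("delta", "beta", "gamma", "theta"),
                      c("Awake", "NREM", "REM"))),
    emg_power_by_state = c(Awake = 1.0, NREM = 0.25, REM = 0.02),
    hrf_true = list(amplitude = 1.0, t_peak = 1.0, shape = 3),
    undershoot_gain = 1,
    vasomotion_sigma = 6.4,
    bilateral_shared_fraction = 0.8,
    state_hbt_offset_uM = c(Awake = 0, NREM = 24, REM = 75),
    evoked_amp_uM = 18.7,
    brief_peak_uM = 5,
    undershoot_uM = 2.2,
    oxy_ratio = 1.3,
    heart_rate_by_state = c(Awake = 10, NREM = 8, REM = 8.5),
    heart_pulse_amp = 0.01,
    baseline_diameter_um = 23,
    diameter_percent_per_uM = 0.5,
    stim_times = NULL,
    stim_period_s = 3600,
    stim_gamma_gain = 2,
    fs_neural = 1000,
    fs_optical = 30,
    seed = 1L) {
  p <- as.list(environment())
  validate_gen_params(p)
  structure(p, class = "gen_params")
}

validate_gen_params <- function(p) {
  m <- p$state_transition_matrix
  if (!is.matrix(m) || any(dim(m) != 3) || any(m < 0) ||
      any(abs(rowSums(m) - 1) > 1e-8)) {
    stop("state_transition_matrix must be 3x3 row-stochastic")
  }
  if (m[1, 3] != 0) stop("REM must only be reachable from NREM (Awake->REM must be 0)")
  if (p$vasomotion_sigma < 0) stop("vasomotion_sigma must be >= 0")
  if (p$bilateral_shared_fraction < 0 || p$bilateral_shared_fraction > 1) {
    stop("bilateral_shared_fraction must lie in [0, 1]")
  }
  if (any(p$band_power_by_state < 0) || any(p$emg_power_by_state < 0)) {
    stop("band powers must be non-negative")
  }
  invisible(p)
}

#' Ablated-physiology parameter preset
#'
#' The counterpart of [gen_params()] emulating targeted removal of the
#' nitric-oxide interneuron population: cortical delta power reduced ~70%,
#' no post-stimulus undershoot, vasomotion amplitude reduced ~40%, and a
#' lower bilateral shared fraction. State-dependent blood-volume offsets are
#' unchanged (state means are preserved).
#'
#' @param ... overrides forwarded to [gen_params()].
#' @return `gen_params` object.
#' @export
gen_params_ablated <- function(...) {
  ctrl <- gen_params()
  bp <- ctrl$band_power_by_state
  bp["delta", ] <- bp["delta", ] * 0.3
  gen_params(band_power_by_state = bp,
             undershoot_gain = 0,
             vasomotion_sigma = ctrl$vasomotion_sigma * 0.6,
             bilateral_shared_fraction = ctrl$bilateral_shared_fraction * 0.75,
             ...)
}

state_levels <- c("Awake", "NREM", "REM")

#' Simulate the arousal-state sequence
#'
#' Draws per-5-s-bin labels from the first-order Markov chain in `params`.
#'
#' @param params [gen_params()].
#' @param n_bins number of 5-s bins (>= 1).
#' @param init initial state name, or `"stationary"` to draw it from the
#'   chain's stationary distribution (default `"Awake"`).
#' @return factor vector of length `n_bins` with levels Awake/NREM/REM.
#' @export
simulate_state_sequence <- function(params, n_bins, init = "Awake") {
  validate_gen_params(params)
  if (n_bins < 1) stop("n_bins must be >= 1")
  m <- params$state_transition_matrix
  out <- integer(n_bins)
  out[1] <- if (identical(init, "stationary")) {
    sample.int(3, 1, prob = stationary_distribution(m))
  } else match(init, state_levels)
  if (n_bins > 1) {
    u <- stats::runif(n_bins - 1)
    cum <- t(apply(m, 1, cumsum))
    for (i in 2:n_bins) {
      out[i] <- 1L + sum(u[i - 1] > cum[out[i - 1], ])
    }
  }
  factor(state_levels[out], levels = state_levels)
}

stationary_distribution <- function(m) {
  e <- eigen(t(m))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# band-limited unit-variance Gaussian noise, per-sample amplitude modulated
band_noise_modulated <- function(n, fs, band, sd_per_sample) {
  if (all(sd_per_sample == 0)) return(numeric(n))
  x <- bandpass(stats::rnorm(n), fs, band, order = 3)
  x <- x / stats::sd(x)
  unname(x * sd_per_sample)
}

per_sample_state <- function(states, fs, bin_s = 5) {
  rep(as.integer(states), each = round(bin_s * fs))
}

#' Synthesize neural channels
#'
#' Builds broadband cortical LFP (left and right), hippocampal LFP, and
#' nuchal EMG as sums of band-limited Gaussian noise whose per-band variance
#' follows `band_power_by_state` for the active state. The EMG band is
#' synthesized over 250 Hz up to 95% of Nyquist (its physiological 300-3000
#' Hz extent is not representable at the default 1 kHz rate; only the
#' envelope matters downstream). Stimulus periods multiply gamma-band
#' variance by `1 + stim_gamma_gain`.
#'
#' @param states per-bin factor from [simulate_state_sequence()].
#' @param params [gen_params()].
#' @param events optional event log (data.frame with `onset_s`,
#'   `duration_s`, `type`); non-auditory stimuli boost gamma power.
#' @return list with `lfp_cortexL`, `lfp_cortexR`, `lfp_hipp`, `emg` at
#'   `fs_neural`, and `fs`.
#' @export
synthesize_neural <- function(states, params, events = NULL) {
  if (length(states) == 0) stop("states must be non-empty")
  fs <- params$fs_neural
  st <- per_sample_state(states, fs)
  n <- length(st)
  bp <- params$band_power_by_state
  bands <- list(delta = c(1, 4), beta = c(13, 30), gamma = c(30, 100))
  gamma_boost <- rep(1, n)
  if (!is.null(events) && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      if (identical(events$type[i], "auditory")) next
      i0 <- floor(events$onset_s[i] * fs) + 1
      i1 <- min(n, i0 + round((events$duration_s[i] + 0.3) * fs))
      if (i0 <= n) gamma_boost[i0:i1] <- 1 + params$stim_gamma_gain
    }
  }
  mk_cortex <- function() {
    x <- numeric(n)
    for (b in names(bands)) {
      amp <- sqrt(bp[b, st])
      if (b == "gamma") amp <- amp * sqrt(gamma_boost)
      x <- x + band_noise_modulated(n, fs, bands[[b]], amp)
    }
    x
  }
  hipp <- band_noise_modulated(n, fs, c(4, 10), sqrt(bp["theta", st]))
  emg_band <- c(250, 0.95 * fs / 2)
  emg <- band_noise_modulated(n, fs, emg_band,
                              sqrt(params$emg_power_by_state[st]))
  list(lfp_cortexL = mk_cortex(), lfp_cortexR = mk_cortex(),
       lfp_hipp = hipp, emg = emg, fs = fs)
}

# calibration of the stimulus-response scales: window means of the unit
# boxcar-convolved kernels for the default response geometry
stim_response_kernels <- function(params, fs) {
  t <- seq(0, 15, by = 1 / fs)
  pos <- gamma_variate(t, 1, 1.0, 3)
  neg <- gamma_variate(t, 1, 3.5, 3)
  list(t = t, pos = pos, neg = neg)
}

stim_response <- function(n, fs, events, params) {
  # noiseless stimulus-transient component of dHbT (uM): a positive lobe
  # (impulse kernel convolved with the stimulus boxcar) plus a delayed
  # undershoot of fixed shape locked to stimulus offset
  kern <- stim_response_kernels(params, fs)
  resp <- numeric(n)
  if (is.null(events) || !nrow(events)) return(resp)
  t <- kern$t
  unit_pos <- function(duration_s) {
    box <- rep(1, max(1L, round(duration_s * fs)))
    conv_causal(c(box, numeric(length(kern$pos))), kern$pos, 1 / fs)
  }
  win_mean <- function(x, t0, t1) mean(x[(round(t0 * fs) + 1):(round(t1 * fs))])
  u5 <- unit_pos(5)
  s_pos <- params$evoked_amp_uM / win_mean(u5, 1.5, 6.5)
  ub <- unit_pos(0.1)
  s_pos_brief <- params$brief_peak_uM / max(ub)
  # undershoot: gamma-variate locked to stimulus offset, scaled so the brief
  # stimulus' 2-4 s window mean equals -undershoot_uM at gain 1
  under_shape <- function(duration_s) {
    gamma_variate(t - duration_s, 1, 2.2, 2.5)
  }
  ub_neg <- under_shape(0.1)
  tail_pos <- s_pos_brief * win_mean(ub, 2, 4)
  s_neg <- (params$undershoot_uM + tail_pos) / win_mean(ub_neg, 2, 4)
  for (i in seq_len(nrow(events))) {
    if (identical(events$type[i], "auditory")) next
    d <- events$duration_s[i]
    pos <- if (d >= 1) u5 else ub
    neg <- if (d >= 1) under_shape(5) else ub_neg
    sp <- if (d >= 1) s_pos else s_pos_brief
    m <- min(length(pos), length(neg))
    shape <- sp * pos[1:m] - params$undershoot_gain * s_neg * neg[1:m]
    i0 <- floor(events$onset_s[i] * fs) + 1
    if (i0 > n) next
    idx <- i0:min(n, i0 + m - 1)
    resp[idx] <- resp[idx] + shape[seq_along(idx)]
  }
  resp
}

#' Synthesize hemodynamics from a neural envelope
#'
#' Blood volume per hemisphere is the sum of (i) the gamma-band power
#' envelope (mean-subtracted) convolved with the true gamma-variate kernel,
#' (ii) a smoothed state-dependent offset, (iii) band-limited (0.05-0.3 Hz)
#' vasomotion noise of SD `vasomotion_sigma` with fraction
#' `bilateral_shared_fraction` of its variance common to both hemispheres,
#' and (iv) stimulus transients with an optional delayed undershoot.
#' Oxy/deoxy are a fixed split (`oxy_ratio`) of the evoked part so
#' `dHbT = dHbO + dHbR` exactly; the arteriole diameter is an affine map of
#' dHbT.
#'
#' @param gamma_envelope numeric vector (shared by both hemispheres) or
#'   two-column matrix (per hemisphere) of gamma-band power at `fs_optical`.
#' @param states per-bin factor; must span the same time as the envelope.
#' @param params [gen_params()].
#' @param events optional event log for stimulus transients.
#' @return list of two-column matrices (`L`, `R`): `dHbT`, `dHbO`, `dHbR`
#'   (uM), `diameter_um`, plus `fs`.
#' @export
synthesize_hemodynamics <- function(gamma_envelope, states, params,
                                    events = NULL) {
  fs <- params$fs_optical
  env <- if (is.matrix(gamma_envelope)) gamma_envelope else
    cbind(gamma_envelope, gamma_envelope)
  n <- nrow(env)
  n_state <- length(states) * 5 * fs
  if (abs(n - n_state) > fs) {
    stop("envelope and state sequence cover different durations")
  }
  st <- per_sample_state(states, fs)[seq_len(n)]
  h <- with(params$hrf_true, gamma_variate(seq(0, 8, by = 1 / fs),
                                           amplitude, t_peak, shape))
  offset <- gaussian_smooth(params$state_hbt_offset_uM[st], 2 * fs)
  f <- params$bilateral_shared_fraction
  shared <- vaso_noise(n, fs)
  stim <- stim_response(n, fs, events, params)
  out <- matrix(0, n, 2)
  for (hemi in 1:2) {
    drive <- conv_causal(env[, hemi] - mean(env[, hemi]), h, 1 / fs)
    vaso <- sqrt(f) * shared + sqrt(1 - f) * vaso_noise(n, fs)
    out[, hemi] <- drive + offset + params$vasomotion_sigma * vaso + stim
  }
  colnames(out) <- c("L", "R")
  dHbO <- params$oxy_ratio * out
  dHbR <- (1 - params$oxy_ratio) * out
  diam <- params$baseline_diameter_um *
    (1 + params$diameter_percent_per_uM / 100 * out)
  list(dHbT = out, dHbO = dHbO, dHbR = dHbR, diameter_um = diam, fs = fs,
       true_kernel = h)
}

vaso_noise <- function(n, fs) {
  if (n < 16) return(numeric(n))
  x <- bandpass(stats::rnorm(n), fs, c(0.05, 0.3), order = 2)
  x / stats::sd(x)
}

default_stim_times <- function(duration_s, stim_period_s) {
  period <- min(duration_s, stim_period_s)
  onsets <- c()
  t <- 15
  while (t < period - 20) {
    onsets <- c(onsets, t)
    t <- t + stats::runif(1, 30, 45)
  }
  if (!length(onsets)) {
    return(data.frame(onset_s = numeric(), type = character(),
                      duration_s = numeric(), side = character()))
  }
  type <- rep(c("brief", "long", "auditory"), length.out = length(onsets))
  data.frame(onset_s = onsets, type = type,
             duration_s = ifelse(type == "long", 5, 0.1),
             side = rep(c("L", "R"), length.out = length(onsets)))
}

#' Simulate a complete multimodal session
#'
#' Orchestrates the generator: state sequence, neural channels, gamma
#' envelopes, hemodynamics, behavioral channels (whisker motion, body force,
#' with awake whisking bouts and REM twitches), heart-rate pulsation, and
#' forward-rendered reflectance/fluorescence. Everything is reproducible
#' from `params$seed`.
#'
#' @param params [gen_params()].
#' @param duration_s session length, seconds (rounded to whole 5-s bins).
#' @param constants [spectroscopy_constants()] for the reflectance render.
#' @param render render reflectance and fluorescence channels (default TRUE;
#'   disable for analyses that only need concentrations).
#' @param init initial state passed to [simulate_state_sequence()] (default
#'   `"stationary"`).
#' @return object of class `recording_session`: `channels` (named list of
#'   traces), `fs` (named rates), `events` (data.frame), `truth` (ground
#'   truth: `states`, `dHbT`/`dHbO`/`dHbR`, `true_kernel`,
#'   `gamma_envelope`, `diameter_um`, `dff_true`, `params`).
#' @export
simulate_session <- function(params = gen_params(), duration_s = 1800,
                             constants = spectroscopy_constants(),
                             render = TRUE, init = "stationary") {
  set.seed(params$seed)
  n_bins <- floor(duration_s / 5)
  states <- simulate_state_sequence(params, n_bins, init = init)
  events <- params$stim_times %||%
    default_stim_times(n_bins * 5, params$stim_period_s)
  neural <- synthesize_neural(states, params, events)
  envL <- band_power_envelope(neural$lfp_cortexL, neural$fs, c(30, 100),
                              fs_out = params$fs_optical)$values
  envR <- band_power_envelope(neural$lfp_cortexR, neural$fs, c(30, 100),
                              fs_out = params$fs_optical)$values
  n_opt <- n_bins * 5 * params$fs_optical
  env <- cbind(envL[seq_len(n_opt)], envR[seq_len(n_opt)])
  hemo <- synthesize_hemodynamics(env, states, params, events)
  beh <- synthesize_behavior(states, params, events)
  truth <- list(states = states, dHbT = hemo$dHbT, dHbO = hemo$dHbO,
                dHbR = hemo$dHbR, diameter_um = hemo$diameter_um,
                true_kernel = hemo$true_kernel, gamma_envelope = env,
                params = params)
  channels <- c(neural[c("lfp_cortexL", "lfp_cortexR", "lfp_hipp", "emg")],
                list(whisker = beh$whisker, force = beh$force))
  fs <- list(neural = params$fs_neural, optical = params$fs_optical,
             behavior = params$fs_optical)
  if (render) {
    rend <- render_session(truth, constants, params)
    channels <- c(channels, rend$channels)
    truth$dff_true <- rend$dff_true
  }
  structure(list(channels = channels, fs = fs, events = events,
                 truth = truth),
            class = "recording_session")
}

synthesize_behavior <- function(states, params, events = NULL) {
  fs <- params$fs_optical
  st <- per_sample_state(states, fs)
  n <- length(st)
  p_whisk <- c(0.35, 0.02, 0.12)[as.integer(states)]  # per-bin bout prob
  amp_whisk <- c(1.0, 0.3, 0.4)
  bout <- rep(stats::runif(length(states)) < p_whisk, each = 5 * fs)
  whisker <- abs(stats::rnorm(n)) * bout * amp_whisk[st] * 2
  if (!is.null(events) && nrow(events)) {
    for (i in seq_len(nrow(events))) {   # stimulus-evoked whisking
      if (identical(events$type[i], "auditory")) next
      i0 <- floor(events$onset_s[i] * fs) + 1
      i1 <- min(n, i0 + round(1.5 * fs))
      if (i0 <= n) whisker[i0:i1] <- pmax(whisker[i0:i1], abs(stats::rnorm(i1 - i0 + 1)) * 2)
    }
  }
  p_loco <- c(0.05, 0.0, 0.0)[as.integer(states)]
  loco <- rep(stats::runif(length(states)) < p_loco, each = 5 * fs)
  force <- abs(stats::rnorm(n)) * loco * 3 + stats::rnorm(n) * 0.05
  list(whisker = whisker, force = force)
}

#' Forward-render optical channels from ground truth
#'
#' Reflectance per wavelength follows the forward Beer-Lambert model (530-nm
#' reflectance additionally carries a heart-rate pulsation used by the sleep
#' scorer); fluorescence is the true calcium signal multiplied by the 530-nm
#' attenuation factor.
#'
#' @param truth ground-truth list (needs `dHbO`, `dHbR`, `gamma_envelope`,
#'   `states`).
#' @param constants [spectroscopy_constants()].
#' @param params [gen_params()].
#' @return list with `channels` (reflectance `refl_<nm>_<L/R>` and
#'   fluorescence `fluor_<L/R>` at `fs_optical`) and `dff_true` (two-column
#'   matrix).
#' @export
render_session <- function(truth, constants, params) {
  fs <- params$fs_optical
  n <- nrow(truth$dHbT)
  st <- per_sample_state(truth$states, fs)[seq_len(n)]
  hr <- gaussian_smooth(params$heart_rate_by_state[st], 2 * fs)
  pulse <- params$heart_pulse_amp * sin(2 * pi * cumsum(hr) / fs)
  channels <- list()
  dff <- matrix(0, n, 2)
  iso <- constants$isosbestic_index
  for (hemi in 1:2) {
    I <- forward_beer_lambert(truth$dHbO[, hemi], truth$dHbR[, hemi], constants)
    env <- truth$gamma_envelope[, hemi]
    dff[, hemi] <- 0.3 * (env - mean(env)) / mean(env)  # true calcium dF/F
    g_atten <- I[, iso] / 1   # I0 = 1: normalized attenuation factor
    for (w in seq_along(constants$wavelengths_nm)) {
      nm <- constants$wavelengths_nm[w]
      tr <- I[, w]
      if (w == iso) tr <- tr * (1 + pulse)
      channels[[paste0("refl_", nm, "_", c("L", "R")[hemi])]] <- tr
    }
    channels[[paste0("fluor_", c("L", "R")[hemi])]] <-
      (1 + dff[, hemi]) * g_atten
  }
  list(channels = channels, dff_true = dff)
}

#' Render a synthetic vessel cross-section frame stack
#'
#' Discs of the true diameter with Gaussian blur and additive noise, for
#' validating the diametry pipeline against ground truth.
#'
#' @param diameter_px per-frame lumen diameter, pixels.
#' @param img_size frame side length, pixels (default 72).
#' @param blur_px Gaussian blur sd, pixels (default 0.5).
#' @param noise_sd additive Gaussian noise sd relative to lumen amplitude 1
#'   (default 0.1); frames are clamped at 0 over a 0.3 background.
#' @return 3-D array `(row, col, frame)`.
#' @export
render_vessel_frames <- function(diameter_px, img_size = 72, blur_px = 0.5,
                                 noise_sd = 0.1) {
  xg <- matrix(rep(seq_len(img_size) - (img_size + 1) / 2, each = img_size),
               img_size, img_size)
  yg <- t(xg)
  k <- NULL
  if (blur_px > 0) {
    k <- stats::dnorm(seq(-ceiling(3 * blur_px), ceiling(3 * blur_px)),
                      sd = blur_px)
    k <- k / sum(k)
  }
  out <- array(0, c(img_size, img_size, length(diameter_px)))
  for (i in seq_along(diameter_px)) {
    img <- (xg^2 + yg^2 <= (diameter_px[i] / 2)^2) * 1.0
    if (!is.null(k)) {
      img <- apply(img, 2, function(col)
        as.numeric(stats::filter(col, k, circular = TRUE)))
      img <- t(apply(img, 1, function(row)
        as.numeric(stats::filter(row, k, circular = TRUE))))
    }
    img <- img + 0.3
    if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
    out[, , i] <- pmax(img, 0)
  }
  out
}

#' @export
print.recording_session <- function(x, ...) {
  nb <- length(x$truth$states)
  cat("<recording_session>", nb, "bins (", nb * 5 / 60, "min )\n")
  cat("  states:", paste(sprintf("%s %.0f%%", state_levels,
      100 * prop.table(table(x$truth$states))), collapse = ", "), "\n")
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  cat("  events:", nrow(x$events), "\n")
  invisible(x)
}
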