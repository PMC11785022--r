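---
title: "Models and methods in nvcoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in nvcoupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nvcoupling)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters with their units
and defaults, what the synthetic generator does and does not emulate, the
numerical choices, and the design decisions that were genuinely open. It
states no empirical result that the test suite does not itself compute.

## 1. Hemoglobin spectroscopy

The imaging model is the modified Beer–Lambert law. For each illumination
wavelength $\lambda$, reflectance $I(\lambda, t)$ relative to an awake-rest
baseline $I_0(\lambda)$ gives an absorbance change
$\Delta A = -\ln(I/I_0)$, modeled as

$$\Delta A(\lambda, t) = \big[\varepsilon_{HbO}(\lambda)\,\Delta HbO(t) +
\varepsilon_{HbR}(\lambda)\,\Delta HbR(t)\big]\, X(\lambda),$$

with molar extinction coefficients $\varepsilon$ (cm$^{-1}$M$^{-1}$) and an
estimated optical pathlength $X(\lambda)$ (cm). With two or more
wavelengths the two concentration changes (μM) are the least-squares
solution; $\Delta HbT = \Delta HbO + \Delta HbR$ then holds as a linear
identity, which the tests assert at machine precision. With a single
isosbestic wavelength (~530 nm, where the two extinctions agree within 2%)
only $\Delta HbT$ is identifiable.

*Constants.* The bundled extinction values at 480/530/630 nm follow the
standard tabulated hemoglobin spectra; pathlengths default to published
widefield estimates (0.04/0.05/0.30 cm). Both are configuration
(`spectroscopy_constants()`, YAML-loadable), not measurements: real
deployments should substitute instrument-calibrated values. Round-trip
correctness is independent of the specific numbers.

*Baseline.* $I_0$ is the mean reflectance over detected awake-rest events
of at least 10 s. Manually selecting short (5 s) awake-rest baselines is
common practice in this field; we reuse the module-wide ≥10 s rest rule
instead, which changes nothing for an unbiased baseline and keeps the
pipeline free of manual steps.

*Fluorescence correction.* Absorption by blood multiplies the collected
fluorescence by approximately the normalized isosbestic reflectance
$G(t)/G_0$. A common shorthand description of this correction — scaling by
the ratio of the channels' resting baseline values — is a time-independent
factor, which cannot remove dynamic contamination; the default here is
division by $G(t)/G_0$, the standard attenuation model and the exact
inverse of the generator's forward contamination, with the static variant
available as
`correct_fluorescence(..., method = "static")`.

## 2. Signal processing

All filters are Butterworth, applied forward-backward (`filtfilt`) so that
envelopes and evoked responses are not delayed; a symmetric pulse stays
symmetric, which the tests assert. Band power envelopes use a 3rd-order
bandpass, squaring, a <1 Hz zero-phase lowpass, and resampling to 30 Hz.
Note that a zero-phase filter applies $|H|^4$ to power, so the effective
noise bandwidth of the 30–100 Hz gamma envelope is ~60 Hz rather than
70 Hz; the envelope tests therefore compare against the filter's own band
variance rather than a brick-wall ideal.

The EMG envelope is bandpassed 300–3000 Hz (truncated at Nyquist with a
warning when the sampling rate cannot represent the band), squared,
Gaussian-smoothed (σ = 0.5 s), log10-transformed with a floor of
$10^{-12}$ a.u., and resampled to 30 Hz.

Spectra and coherence are multitaper estimates over DPSS (Slepian) tapers.
The one-sided density integrates to the signal variance (Parseval, asserted
within 5%). Coherence pools tapers across events; for 10-s rest events the
default is NW = 3, K = 5, and spectrograms use a 5-s window, 0.2-s step,
NW = 5, K = 9. For tapers longer than 1024 samples the Slepian sequences
are computed exactly at 1024, spline-interpolated and re-orthonormalized —
the concentration loss is negligible at these bandwidths, and orthonormality
is asserted in the tests. Detrending removes the per-event best-fit line.

Resampling to 30 Hz is an anti-aliased lowpass (0.45 of the target Nyquist)
followed by linear interpolation; a polyphase implementation would be
equivalent in band and this form is exact for the non-integer 1000/30
ratio.

Heart rate is the per-5-s-bin spectral peak of the isosbestic reflectance
within 5–14 Hz (the murine pulse band), with bins lacking a peak five times
the in-band median marked missing. There is no single standard extraction
method for this channel; the spectral-peak rule is a documented stand-in
with the right selectivity for the scoring features.

## 3. Arousal-state scoring

Features per 5-s bin: cortical delta (1–4 Hz), beta (13–30 Hz), gamma
(30–100 Hz) power, hippocampal theta (4–10 Hz) power (multitaper, computed
on traces decimated to 250 Hz for speed — all bands lie below 100 Hz), EMG
log power, heart rate, and whisking duration. The whisking threshold is
3 SD of the whisker-motion signal during quiescence, re-estimated once; an
adaptive rule, so the features are scale-free in the motion units.

The classifier is a bootstrap-aggregated forest of CART trees (Gini
splitting, `mtry = ceiling(sqrt(p))`, stratified bootstrap, 128 trees by
default), validated by out-of-bag error. No tree learner is available among
the package's allowed dependencies, so the forest is implemented here;
it is deliberately plain — no class weights or pruning — because the
feature separation does the work. On permuted labels the OOB error of a
deep forest sits between the majority-vote chance rate and the Gini rate;
the tests assert a band just above chance rather than exact equality.

Segmentation rules are hard-coded: Alert/Asleep
15-min blocks by the >80% rule (blocks meeting neither are `Neither` and
excluded from block analyses), rest events ≥10 s of motion-free wakefulness,
NREM events ≥30 s, REM events ≥60 s, transitions 30 s of one state followed
by 30 s of another, and an optional exclusion of the initial stimulation
hour (`exclude_first_s`).

## 4. Event analysis and the HRF

Triggered averages subtract each trial's mean over the 2 s before onset and
smooth with a 3rd-order Savitzky–Golay filter; the window length (17
samples at 30 Hz, ~0.57 s) is a package default chosen to smooth without
flattening second-scale responses, and the tests bound its boxcar
distortion below 2%. The neurovascular slope
is the through-origin least-squares slope $\sum xy / \sum x^2$. State
summaries lowpass each event below 1 Hz (4th order, zero phase) before the
per-event mean or variance; variance is computed on the same filtered
traces so that means and variances describe the same band.
Transition deltas are the mean over +10..+30 s minus −30..−10 s around the
transition.

The HRF is estimated by least squares on the Toeplitz system
$\Delta HbT \approx X(P_\gamma)\,h$ over a 5-s kernel support with a ridge
stabilizer $\lambda \cdot \mathrm{tr}(X^TX)/p$, $\lambda = 10^{-3}$
(package defaults: 5 s covers the kernel mass, and the ridge only matters
for ill-conditioned envelopes). The design uses only rows with
full lag history plus an unpenalized intercept, so at $\lambda = 0$
deconvolution is the exact inverse of convolution — asserted to $10^{-6}$.
The kernel is then fit with the gamma-variate form
$h(t) = A\,(t/t_p)^\alpha e^{\alpha(1 - t/t_p)}$ (multi-start Nelder–Mead
over a $t_p$ grid; this parameterization makes the time-to-peak directly
interpretable). Train/test is a deterministic first-half/second-half split;
predictive $R^2$ is computed on the held-out half after discarding the
kernel-length warm-up.

## 5. Vessel diametry

Surface vessels: the intensity profile across a rectangular box is averaged
along the vessel axis and the diameter is the full width at half maximum,
with background taken as the mean of the outer 10% of samples and sub-pixel
crossings by linear interpolation. Note the FWHM of an ideal cylindrical
lumen profile ($\propto$ chord length) is $\sqrt{3}/2 \approx 0.87$ of the
true diameter; FWHM is a consistent *relative* diameter measure, which is
all percent-change analyses need.

Penetrating vessels: thresholding in Radon space. The frame is projected
over 0–179° (half-pixel offset sampling), each background-subtracted
projection is smoothed (σ = 1 px) and binarized at 0.5 of its own maximum,
the binary sinogram is reconstructed by Ram–Lak filtered backprojection
(real-space kernel formulation; reconstruction on a 2× grid for sub-pixel
area counting), the reconstruction is thresholded at 0.2 of its maximum,
and the equivalent diameter $2\sqrt{A/\pi}$ of the hole-filled connected
component containing the centroid is reported. Thresholding a projection at
fraction $t$ of its maximum truncates an elliptical lumen's support by
exactly $\sqrt{1-t^2}$, so the diameter is divided by $\sqrt{1-t^2}$ — an
exact compensation for elliptical cross sections that removes the 13%
systematic underestimate on sharp lumens. The thresholds (0.5, 0.2) follow
the cited algorithm's convention; they are exposed, not tuned. Frames are
rigidly registered (integer-pixel, FFT cross-correlation against the median
frame) before measurement, and frames with no valid component are dropped
and counted rather than interpolated.

## 6. The synthetic generator: what a green test establishes

`gen_params()` states the generative world:

- **State sequence**: a first-order Markov chain over Awake/NREM/REM in 5-s
  bins, REM reachable only from NREM. Defaults give stationary occupancy
  ≈ 0.40/0.51/0.09 with ~10-min awake bouts and composite sleep episodes
  (REM may return to NREM), enough to produce both Alert and Asleep 15-min
  blocks in an hour-scale session. Dwell times are whatever the chain
  implies; a Markov chain is the minimal generative structure the 5-s
  scoring assumes.
- **Neural channels**: sums of band-limited Gaussian noise whose per-band
  variance follows `band_power_by_state` (delta elevated ~4x in NREM, theta
  ~3.5x in REM, EMG power 1/0.25/0.02 — atonia in REM). The EMG is
  synthesized at envelope-relevant bandwidth (250 Hz up to 95% of Nyquist):
  its full 300–3000 Hz physiological extent is not representable at the
  1 kHz default rate and only the envelope feeds downstream analyses.
- **Hemodynamics** (μM): gamma-envelope convolved with a gamma-variate
  kernel (peak 1 s, shape 3), state offsets (+24 NREM, +75 REM, smoothed
  2 s), vasomotion as 0.05–0.3 Hz noise with SD 6.4 μM (resting variance
  ≈ 41 μM²), stimulus transients calibrated so a 5-s stimulus averages
  18.7 μM over 1.5–6.5 s, a brief stimulus peaks at ~5 μM, and the
  offset-locked undershoot makes the brief 2–4 s window −2.2 μM at gain 1.
  The oxygenation split is fixed: ΔHbO = 1.3 ΔHbT, ΔHbR = −0.3 ΔHbT,
  matching the sign structure of evoked oxy/deoxy responses. A fraction
  (default 0.8) of the stochastic drive is shared across hemispheres, so
  resting bilateral correlation ≈ 0.8.
- **Rendering**: reflectance by the forward Beer–Lambert model (with an
  optional heart-rate pulsation on the isosbestic channel used by the
  scorer — disable it for noiseless round-trip checks), fluorescence as the
  true calcium signal times the 530-nm attenuation, vessel frames as
  blurred noisy discs of the true diameter.

The generator emulates the *statistical structure the analyses assume*:
state-dependent band powers, linear neurovascular coupling, additive
vasomotion, shared bilateral drive. It does **not** emulate biophysical
vascular dynamics, optics (no Monte-Carlo, no scattering), pupil or
open-field behavior, electrode artifacts, or nonstationarity within states.
A green pipeline test therefore establishes correctness of the analysis
chain on data satisfying its own model assumptions — not robustness to the
many ways real data violate them.

The "ablated" preset (`gen_params_ablated()`) reduces delta power ~70%,
removes the undershoot, reduces vasomotion ~40% and the shared fraction by
a quarter, while leaving state offsets untouched; the acceptance suite
checks that the full pipeline reproduces the direction of every headline
contrast between the two presets, including the null contrasts.

## 7. Numerical choices and degenerate inputs

- Filters pad by odd reflection over ~6 time constants of the slowest
  corner before forward-backward filtering.
- The EMG log floor is $10^{-12}$ a.u.; zero input returns the floor.
- Gamma-variate fitting optimizes over log-parameters (positivity), with
  multi-start $t_p \in \{0.25, 0.5, 1, 1.5, 2, 3\}$ s; an all-zero kernel
  short-circuits to a flagged degenerate fit.
- Heart-rate bins with no prominent peak, diametry frames with no
  half-height crossing or empty component, and states with no events yield
  `NA`/omitted rows, never silent zeros.
- `power_sample_size()` uses the two-sided normal-approximation formula
  $n = 2((z_{1-\alpha/2}+z_{\beta})/d)^2$ rounded up.

## 8. Infrastructure substitutions

No HDF5, TIFF, or tree-learner bindings exist among the permitted
dependencies, so: sessions are stored as a plain-text directory (CSV
channel tables, CSV event log, JSON metadata/ground-truth sidecar) behind
`write_session()`/`read_session()`; vessel stacks are passed as in-memory
arrays (and rendered on demand); and the bagged forest is implemented in
the package. The module surfaces match what an HDF5-backed implementation
would expose, so swapping the store later is localized to `io.R`.

## 9. Known limitations

- The chord-geometry TiRS correction is exact for elliptical lumens only;
  strongly non-convex or annular cross sections will bias it.
- FWHM and (corrected) TiRS measure different functionals of a vessel
  image; on the same cross-section image they agree (tested within 10%),
  but FWHM of a *tube profile* underestimates the true diameter by up to
  13% by construction.
- The classifier is trained per-session on ground-truth labels in the
  synthetic world; applying it to real data requires a labeled training
  session and feature distributions comparable across sessions.
- Coherence segments must share one length; events are truncated to the
  shortest (or a stated) length, discarding the tails of longer events.
- The Markov state model cannot produce both very long consolidated wake
  and frequent brief arousals with one awake state; block-level analyses on
  synthetic data inherit that simplification.
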