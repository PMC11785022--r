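Package: nvcoupling
Title: Neurovascular Coupling and Arousal-State Analysis of Multimodal
    Cortical Recordings
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for head-fixed mouse experiments combining
    widefield intrinsic optical signal imaging, local field potential and
    electromyography recordings, and two-photon vessel imaging. Converts
    multi-wavelength reflectance to hemoglobin concentration changes via the
    modified Beer-Lambert law, corrects fluorescence for hemodynamic
    attenuation, extracts band-limited power envelopes, estimates multitaper
    spectra and coherence, scores arousal state (Awake/NREM/REM) in 5-second
    bins with a bagged decision forest, measures stimulus-evoked responses
    and neurovascular coupling (cross-correlation, through-origin slope,
    hemodynamic response function deconvolution with gamma-variate fits),
    quantifies resting-state vasomotion and interhemispheric coherence, and
    measures single-vessel diameters by full-width-at-half-maximum and
    thresholding in Radon space. Includes a synthetic multimodal session
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
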