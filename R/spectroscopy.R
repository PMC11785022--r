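# Modified Beer-Lambert hemoglobin spectroscopy and fluorescence correction.
#
# The imaging model per wavelength is
#   I(lambda, t) = I0(lambda) * exp(-dA(lambda, t)),
#   dA = (eps_HbO * dHbO + eps_HbR * dHbR) * X(lambda) * 1e-6
# with concentrations in micromolar, extinction coefficients in 1/(cm*M) and
# pathlengths X in cm.

#' Spectroscopy constants
#'
#' Bundles extinction coefficients and estimated optical pathlengths per
#' wavelength. Defaults use standard tabulated hemoglobin spectra at the
#' three illumination wavelengths (480/530/630 nm; 530 nm is near-isosbestic)
#' and published widefield pathlength estimates; both are configuration, not
#' measurements, and can be overridden (e.g. from a YAML config, see
#' [read_spectroscopy_config()]).
#'
#' @param wavelengths_nm illumination wavelengths, nm.
#' @param epsilon_hbo,epsilon_hbr molar extinction coefficients per
#'   wavelength, 1/(cm*M).
#' @param pathlength_cm estimated optical pathlength per wavelength, cm.
#' @param baseline_total_hb_uM assumed baseline total hemoglobin
#'   concentration, micromolar (used only for attenuation scaling summaries).
#' @return object of class `spectroscopy_constants`.
#' @export
spectroscopy_constants <- function(
    wavelengths_nm = c(480, 530, 630),
    epsilon_hbo = c(14550, 39500, 610),
    epsilon_hbr = c(26629, 39036, 5149),
    pathlength_cm = c(0.04, 0.05, 0.30),
    baseline_total_hb_uM = 100) {
  stopifnot(length(epsilon_hbo) == length(wavelengths_nm),
            length(epsilon_hbr) == length(wavelengths_nm),
            length(pathlength_cm) == length(wavelengths_nm))
  if (any(epsilon_hbo <= 0) || any(epsilon_hbr <= 0)) {
    stop("extinction coefficients must be positive")
  }
  iso <- which.min(abs(wavelengths_nm - 530))
  rel <- abs(epsilon_hbo[iso] - epsilon_hbr[iso]) /
    mean(c(epsilon_hbo[iso], epsilon_hbr[iso]))
  if (rel > 0.02) {
    stop("extinction coefficients at the isosbestic wavelength differ by more than 2%")
  }
  structure(list(wavelengths_nm = wavelengths_nm, epsilon_hbo = epsilon_hbo,
                 epsilon_hbr = epsilon_hbr, pathlength_cm = pathlength_cm,
                 baseline_total_hb_uM = baseline_total_hb_uM,
                 isosbestic_index = iso),
            class = "spectroscopy_constants")
}

#' Read spectroscopy constants from a YAML config
#'
#' @param path YAML file with fields `wavelengths_nm`, `epsilon_hbo`,
#'   `epsilon_hbr`, `pathlength_cm`, optionally `baseline_total_hb_uM`.
#' @return `spectroscopy_constants`.
#' @export
read_spectroscopy_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(spectroscopy_constants, cfg)
}

#' Change in absorbance from reflectance
#'
#' `dA = -log(I / I0)` per wavelength; `I0` is the mean reflectance over the
#' awake-rest baseline period.
#'
#' @param I reflectance trace (or matrix, one column per wavelength).
#' @param I0 baseline reflectance, scalar per wavelength.
#' @return dA, same shape as `I` (dimensionless).
#' @export
delta_absorbance <- function(I, I0) {
  if (any(I <= 0) || any(I0 <= 0)) stop("intensities must be positive")
  if (is.matrix(I)) {
    sweep(-log(I), 2, -log(I0), `-`)
  } else {
    -log(I / I0)
  }
}

#' Invert the modified Beer-Lambert model
#'
#' Least-squares inversion of `dA(lambda) = (eps_HbO*dHbO + eps_HbR*dHbR) *
#' X(lambda) * 1e-6` for concentration changes in micromolar. With a single
#' (isosbestic) wavelength only total hemoglobin is identifiable:
#' `dHbT = dA / (eps * X * 1e-6)` using the mean of the two extinction
#' coefficients, and `dHbO`/`dHbR` are returned as `NA`.
#'
#' @param dA matrix of absorbance changes, `time x wavelength` (or a vector
#'   for single-wavelength mode).
#' @param constants [spectroscopy_constants()].
#' @param wavelengths which wavelengths (nm) the columns of `dA` correspond
#'   to; defaults to all in `constants`.
#' @return object of class `hemoglobin_set`: list of micromolar traces
#'   `dHbT`, `dHbO`, `dHbR` with `dHbT == dHbO + dHbR` exactly in the
#'   multi-wavelength mode.
#' @export
invert_beer_lambert <- function(dA, constants = spectroscopy_constants(),
                                wavelengths = constants$wavelengths_nm) {
  if (!is.matrix(dA)) dA <- matrix(dA, ncol = 1)
  idx <- match(wavelengths, constants$wavelengths_nm)
  if (anyNA(idx)) stop("unknown wavelength requested")
  if (ncol(dA) != length(idx)) stop("dA columns must match wavelengths")
  X <- constants$pathlength_cm[idx]
  if (ncol(dA) == 1) {
    eps <- mean(c(constants$epsilon_hbo[idx], constants$epsilon_hbr[idx]))
    dHbT <- as.numeric(dA) / (eps * X * 1e-6)
    return(structure(list(dHbT = dHbT, dHbO = rep(NA_real_, length(dHbT)),
                          dHbR = rep(NA_real_, length(dHbT))),
                     class = "hemoglobin_set"))
  }
  design <- cbind(constants$epsilon_hbo[idx] * X,
                  constants$epsilon_hbr[idx] * X) * 1e-6
  if (rcond_2col(design) < 1e-10) {
    stop("extinction vectors are collinear; inversion is ill-conditioned")
  }
  sol <- qr.solve(design, t(dA))        # 2 x time
  dHbO <- sol[1, ]; dHbR <- sol[2, ]
  structure(list(dHbT = dHbO + dHbR, dHbO = dHbO, dHbR = dHbR),
            class = "hemoglobin_set")
}

rcond_2col <- function(m) {
  s <- svd(m, nu = 0, nv = 0)$d
  s[length(s)] / s[1]
}

#' Forward Beer-Lambert render
#'
#' Generates per-wavelength reflectance from concentration traces; the exact
#' inverse of [invert_beer_lambert()] for noiseless input.
#'
#' @param dHbO,dHbR micromolar traces.
#' @param constants [spectroscopy_constants()].
#' @param I0 baseline intensity per wavelength (default 1).
#' @return `time x wavelength` reflectance matrix.
#' @export
forward_beer_lambert <- function(dHbO, dHbR, constants = spectroscopy_constants(),
                                 I0 = rep(1, length(constants$wavelengths_nm))) {
  if (any(I0 <= 0)) stop("baseline intensities must be positive")
  design <- cbind(constants$epsilon_hbo * constants$pathlength_cm,
                  constants$epsilon_hbr * constants$pathlength_cm) * 1e-6
  dA <- cbind(dHbO, dHbR) %*% t(design)   # time x wavelength
  I <- sweep(exp(-dA), 2, I0, `*`)
  if (any(I <= 0)) stop("render produced non-positive intensities")
  I
}

#' Correct fluorescence for hemodynamic attenuation
#'
#' Divides raw fluorescence by the normalized isosbestic (530-nm) reflectance
#' `G(t)/G0`, removing the multiplicative absorption artifact, then forms
#' dF/F against the baseline mean of the corrected trace:
#' `dFF(t) = (F(t)/(G(t)/G0) - F0bar) / F0bar`.
#'
#' A literal time-independent variant (scaling by the constant baseline
#' ratio only, which cannot remove dynamic contamination) is available with
#' `method = "static"` for comparison.
#'
#' @param F_raw raw fluorescence trace.
#' @param G 530-nm reflectance trace, same length.
#' @param G0 baseline (awake-rest) mean of `G`.
#' @param baseline_idx indices defining the fluorescence baseline period
#'   (default: all samples).
#' @param method `"dynamic"` (default) or `"static"`.
#' @return corrected dF/F trace (unitless).
#' @export
correct_fluorescence <- function(F_raw, G, G0, baseline_idx = seq_along(F_raw),
                                 method = c("dynamic", "static")) {
  method <- match.arg(method)
  if (any(G <= 0) || G0 <= 0) stop("reflectance must be positive")
  if (length(F_raw) != length(G)) stop("fluorescence and reflectance must align")
  Fc <- if (method == "dynamic") F_raw / (G / G0) else F_raw * mean(G[baseline_idx]) / G0
  F0 <- mean(Fc[baseline_idx])
  (Fc - F0) / F0
}

#' @export
print.hemoglobin_set <- function(x, ...) {
  cat("<hemoglobin_set>", length(x$dHbT), "samples\n")
  cat("  dHbT range:", signif(range(x$dHbT), 3), "uM\n")
  invisible(x)
}
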