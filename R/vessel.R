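# Single-vessel diametry: full-width-at-half-maximum for surface vessels
# (profile averaging) and thresholding in Radon space (TiRS) for penetrating
# vessel cross sections, plus rigid frame registration and trace summaries.

#' Full-width-at-half-maximum diameter
#'
#' Width of the lumen intensity profile at half height. Background is the
#' mean of the outer 10% of samples at each end; half height is
#' `background + 0.5 * (peak - background)`; crossings are located with
#' sub-pixel linear interpolation.
#'
#' @param profile averaged intensity profile (vector).
#' @param pixel_size_um microns per pixel (default 1, returning pixels).
#' @return diameter in microns, or `NA` with a warning when no half-height
#'   crossing exists on either side of the peak.
#' @export
fwhm_diameter <- function(profile, pixel_size_um = 1) {
  n <- length(profile)
  if (n < 5) stop("profile too short")
  m <- max(1L, floor(0.1 * n))
  bg <- mean(c(profile[seq_len(m)], profile[(n - m + 1):n]))
  ipk <- which.max(profile)
  half <- bg + 0.5 * (profile[ipk] - bg)
  left <- cross_at(profile, ipk, half, dir = -1L)
  right <- cross_at(profile, ipk, half, dir = +1L)
  if (is.na(left) || is.na(right)) {
    warning("no half-height crossing found; frame marked invalid", call. = FALSE)
    return(NA_real_)
  }
  (right - left) * pixel_size_um
}

cross_at <- function(p, ipk, half, dir) {
  i <- ipk
  while (i + dir >= 1 && i + dir <= length(p)) {
    j <- i + dir
    if (p[j] <= half) {
      # linear interpolation between samples i and j
      frac <- (p[i] - half) / (p[i] - p[j])
      return(i + dir * frac)
    }
    i <- j
  }
  NA_real_
}

bilinear_sample <- function(img, x, y) {
  # img indexed [row, col] = [y, x]; x/y are 1-based continuous coordinates
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- numeric(length(x))
  get_px <- function(yy, xx) {
    ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
    v <- numeric(length(xx))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  val <- get_px(y0, x0) * (1 - fx) * (1 - fy) +
    get_px(y0, x0 + 1) * fx * (1 - fy) +
    get_px(y0 + 1, x0) * (1 - fx) * fy +
    get_px(y0 + 1, x0 + 1) * fx * fy
  val
}

#' Radon transform
#'
#' Line-integral projections of an image over a set of angles, sampled by
#' bilinear interpolation. Offsets span the image diagonal so no mass is
#' clipped.
#'
#' @param img numeric matrix.
#' @param angles_deg projection angles in degrees (default `0:179`).
#' @param ds offset sampling step in pixels (default 0.5 for sub-pixel edge
#'   localization).
#' @return list with `sinogram` (`offset x angle`), `offsets` (pixels,
#'   centered), `angles_deg`.
#' @export
radon_transform <- function(img, angles_deg = 0:179, ds = 0.5) {
  nr <- nrow(img); nc <- ncol(img)
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  half <- ceiling(sqrt(nr^2 + nc^2) / 2)
  offs <- seq(-half, half, by = ds)
  tt <- seq(-half, half, by = 1)
  sino <- matrix(0, length(offs), length(angles_deg))
  for (ai in seq_along(angles_deg)) {
    th <- angles_deg[ai] * pi / 180
    # sample grid: point = center + s*normal + t*direction
    sx <- outer(offs * cos(th), -tt * sin(th), `+`) + cx
    sy <- outer(offs * sin(th), tt * cos(th), `+`) + cy
    sino[, ai] <- rowSums(matrix(bilinear_sample(img, as.numeric(sx),
                                                 as.numeric(sy)),
                                 length(offs), length(tt)))
  }
  list(sinogram = sino, offsets = offs, angles_deg = angles_deg)
}

#' Filtered backprojection (inverse Radon transform)
#'
#' Ramp-filtered backprojection of a sinogram produced by
#' [radon_transform()] (or a binarized version of one).
#'
#' @param sino sinogram matrix (`offset x angle`).
#' @param offsets offset coordinates (pixels, centered).
#' @param angles_deg projection angles, degrees.
#' @param dim output image size `c(nrow, ncol)` in original pixels.
#' @param upsample reconstruction grid refinement factor (default 1).
#' @return reconstructed image matrix (`dim * upsample`).
#' @export
iradon_fbp <- function(sino, offsets, angles_deg, dim, upsample = 1) {
  ns <- nrow(sino)
  nfft <- stats::nextn(2 * ns, 2)
  # Ram-Lak filter built from its real-space kernel (Kak & Slaney), which
  # avoids the DC bias of a naive frequency-domain ramp
  nn <- c(0:(nfft / 2), (nfft / 2 - 1):1)
  h <- numeric(nfft)
  h[1] <- 1 / 4
  odd <- which(nn %% 2 == 1)
  h[odd] <- -1 / (pi * nn[odd])^2
  ramp <- 2 * Re(stats::fft(h))
  filt <- apply(sino, 2, function(p) {
    P <- stats::fft(c(p, rep(0, nfft - ns)))
    Re(stats::fft(P * ramp, inverse = TRUE))[seq_len(ns)] / nfft
  })
  nr <- dim[1] * upsample; nc <- dim[2] * upsample
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  xg <- matrix(rep((seq_len(nc) - cx) / upsample, each = nr), nr, nc)
  yg <- matrix(rep((seq_len(nr) - cy) / upsample, nc), nr, nc)
  out <- matrix(0, nr, nc)
  s0 <- offsets[1]; ds <- offsets[2] - offsets[1]
  for (ai in seq_along(angles_deg)) {
    th <- angles_deg[ai] * pi / 180
    s <- xg * cos(th) + yg * sin(th)
    si <- (s - s0) / ds + 1
    i0 <- floor(si); fr <- si - i0
    ok <- i0 >= 1 & i0 < ns
    acc <- numeric(length(si))
    acc[ok] <- filt[i0[ok], ai] * (1 - fr[ok]) + filt[i0[ok] + 1, ai] * fr[ok]
    out <- out + matrix(acc, nr, nc)
  }
  out * pi / (2 * length(angles_deg))
}

label_component <- function(mask, seed_rc) {
  # connected component (4-neighborhood) of `mask` containing seed; BFS
  nr <- nrow(mask); nc <- ncol(mask)
  if (!mask[seed_rc[1], seed_rc[2]]) return(matrix(FALSE, nr, nc))
  comp <- matrix(FALSE, nr, nc)
  queue <- matrix(seed_rc, ncol = 2)
  comp[seed_rc[1], seed_rc[2]] <- TRUE
  while (nrow(queue) > 0) {
    r <- queue[, 1]; c <- queue[, 2]
    nbr <- rbind(cbind(r - 1, c), cbind(r + 1, c), cbind(r, c - 1), cbind(r, c + 1))
    ok <- nbr[, 1] >= 1 & nbr[, 1] <= nr & nbr[, 2] >= 1 & nbr[, 2] <= nc
    nbr <- nbr[ok, , drop = FALSE]
    new <- mask[nbr] & !comp[nbr]
    nbr <- unique(nbr[new, , drop = FALSE])
    comp[nbr] <- TRUE
    queue <- nbr
  }
  comp
}

#' Thresholding-in-Radon-space (TiRS) diameter
#'
#' Measures the cross-sectional diameter of a penetrating vessel lumen:
#' Radon transform over 0-179 degrees; each angle's projection thresholded at
#' `radon_threshold` of its own maximum; filtered backprojection of the
#' binarized sinogram; result thresholded at `image_threshold` of its
#' maximum; the area `A` of the connected component containing the lumen
#' centroid gives the equivalent diameter `2*sqrt(A/pi)`.
#'
#' Thresholding a projection at a fraction `t` of its maximum truncates the
#' support of an elliptical lumen by exactly `sqrt(1 - t^2)` (the chord of a
#' disc reaches `t` of its maximum at offset `sqrt(1 - t^2) * r`), so the raw
#' Radon-space area underestimates a sharp lumen by the factor `1 - t^2`.
#' With `threshold_correction = TRUE` (default) the equivalent diameter is
#' divided by `sqrt(1 - t^2)`, which is exact for elliptical cross sections
#' (every projection of an ellipse is a scaled disc projection) and removes
#' the bias on sharp-edged lumens.
#'
#' @param img cross-section frame (numeric matrix, lumen bright and roughly
#'   centered).
#' @param radon_threshold fraction of each projection's maximum (default 0.5).
#' @param image_threshold fraction of the reconstruction maximum (default 0.2).
#' @param pixel_size_um microns per pixel (default 1).
#' @param threshold_correction apply the chord-geometry bias compensation
#'   (default TRUE).
#' @param projection_smooth_px Gaussian smoothing (sd, pixels) applied to
#'   each background-subtracted projection before thresholding; suppresses
#'   noise-driven widening of the thresholded support (default 1).
#' @param upsample reconstruction grid refinement for sub-pixel area counting
#'   (default 2).
#' @return equivalent diameter in microns, or `NA` with a warning when the
#'   component is empty.
#' @export
tirs_diameter <- function(img, radon_threshold = 0.5, image_threshold = 0.2,
                          pixel_size_um = 1, threshold_correction = TRUE,
                          projection_smooth_px = 1, upsample = 2) {
  if (any(img < 0)) stop("image must be non-negative")
  rt <- radon_transform(img)
  # remove the background pedestal (median line integral) per projection so
  # the relative threshold refers to the lumen signal, not lumen + background
  sino <- pmax(sweep(rt$sinogram, 2, apply(rt$sinogram, 2, stats::median)), 0)
  if (projection_smooth_px > 0) {
    ds <- rt$offsets[2] - rt$offsets[1]
    sino <- apply(sino, 2, gaussian_smooth,
                  sd_samples = projection_smooth_px / ds)
  }
  sino_bin <- sweep(sino, 2, apply(sino, 2, max) * radon_threshold, `>=`)
  rec <- iradon_fbp(sino_bin * 1, rt$offsets, rt$angles_deg, dim(img),
                    upsample = upsample)
  mask <- rec >= image_threshold * max(rec)
  # seed at the mask pixel nearest the mask centroid (the reconstruction of a
  # binarized sinogram can dip just below threshold at the exact center)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("empty component; frame marked invalid", call. = FALSE)
    return(NA_real_)
  }
  ctr <- colMeans(idx)
  seed <- idx[which.min((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2), ]
  comp <- fill_holes(label_component(mask, seed))
  area <- sum(comp) / upsample^2
  if (area == 0) {
    warning("empty component; frame marked invalid", call. = FALSE)
    return(NA_real_)
  }
  d <- 2 * sqrt(area / pi) * pixel_size_um
  if (threshold_correction) d <- d / sqrt(1 - radon_threshold^2)
  d
}

#' Diameter trace from a cross-section frame stack
#'
#' Registers the stack rigidly to its median frame and measures each frame
#' with [tirs_diameter()]; invalid frames are dropped (returned as `NA`) and
#' counted.
#'
#' @param frames 3-D array `(row, col, frame)`.
#' @param pixel_size_um microns per pixel.
#' @param register rigidly register frames first (default TRUE).
#' @param ... passed to [tirs_diameter()].
#' @return numeric diameter trace (microns), with attribute `n_invalid`.
#' @export
measure_vessel_stack <- function(frames, pixel_size_um = 1, register = TRUE,
                                 ...) {
  if (register) frames <- register_frames(frames)$frames
  d <- vapply(seq_len(dim(frames)[3]), function(i) {
    tryCatch(suppressWarnings(
      tirs_diameter(frames[, , i], pixel_size_um = pixel_size_um, ...)),
      error = function(e) NA_real_)
  }, numeric(1))
  attr(d, "n_invalid") <- sum(is.na(d))
  d
}

fill_holes <- function(comp) {
  # a hole is any FALSE region not connected to the image border
  nr <- nrow(comp); nc <- ncol(comp)
  outside <- matrix(FALSE, nr, nc)
  inv <- !comp
  border <- rbind(cbind(1, which(inv[1, ])), cbind(nr, which(inv[nr, ])),
                  cbind(which(inv[, 1]), 1), cbind(which(inv[, nc]), nc))
  if (nrow(border) > 0) {
    queue <- unique(border)
    outside[queue] <- TRUE
    while (nrow(queue) > 0) {
      r <- queue[, 1]; c <- queue[, 2]
      nbr <- rbind(cbind(r - 1, c), cbind(r + 1, c),
                   cbind(r, c - 1), cbind(r, c + 1))
      ok <- nbr[, 1] >= 1 & nbr[, 1] <= nr & nbr[, 2] >= 1 & nbr[, 2] <= nc
      nbr <- nbr[ok, , drop = FALSE]
      new <- inv[nbr] & !outside[nbr]
      nbr <- unique(nbr[new, , drop = FALSE])
      outside[nbr] <- TRUE
      queue <- nbr
    }
  }
  comp | (inv & !outside)
}

#' Rigid integer-pixel registration of a frame stack
#'
#' Aligns each frame to the median frame by the integer x-y shift maximizing
#' the FFT cross-correlation.
#'
#' @param frames 3-D array `(row, col, frame)`.
#' @param max_shift largest allowed shift in pixels (default 10).
#' @return list with `frames` (registered array, shifted-in regions filled
#'   with the frame median) and `shifts` (`frame x 2` matrix).
#' @export
register_frames <- function(frames, max_shift = 10) {
  ref <- apply(frames, c(1, 2), stats::median)
  nr <- nrow(ref); nc <- ncol(ref)
  Fr <- stats::fft(ref)
  shifts <- matrix(0L, dim(frames)[3], 2)
  out <- frames
  for (i in seq_len(dim(frames)[3])) {
    cc <- Re(stats::fft(Fr * Conj(stats::fft(frames[, , i])), inverse = TRUE))
    dr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
    dc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
    ok_r <- abs(dr) <= max_shift; ok_c <- abs(dc) <= max_shift
    sub <- cc[ok_r, ok_c, drop = FALSE]
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    sh <- c(dr[ok_r][w[1]], dc[ok_c][w[2]])
    shifts[i, ] <- sh
    out[, , i] <- shift_image(frames[, , i], sh)
  }
  list(frames = out, shifts = shifts)
}

shift_image <- function(img, sh) {
  out <- matrix(stats::median(img), nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) - sh[1]
  src_c <- seq_len(ncol(img)) - sh[2]
  ok_r <- src_r >= 1 & src_r <= nrow(img)
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Summarize a diameter trace
#'
#' Percent change relative to the baseline mean, and resting variance as the
#' mean across rest events of the per-event variance of percent change.
#'
#' @param diameter_um diameter trace, microns.
#' @param fs frame rate, Hz.
#' @param rest_events data.frame with `onset_s`, `duration_s` columns; events
#'   shorter than 10 s are ignored.
#' @param baseline_idx indices defining the baseline (default: all frames).
#' @return object of class `diameter_trace`: `diameter_um`, `percent_change`,
#'   `resting_variance` (%^2, `NA` when no usable rest event), `n_invalid`.
#' @export
summarize_diameter <- function(diameter_um, fs, rest_events = NULL,
                               baseline_idx = seq_along(diameter_um)) {
  valid <- !is.na(diameter_um)
  d0 <- mean(diameter_um[baseline_idx], na.rm = TRUE)
  pc <- 100 * (diameter_um - d0) / d0
  rv <- NA_real_
  if (!is.null(rest_events) && nrow(rest_events) > 0) {
    keep <- rest_events$duration_s >= 10
    vars <- c()
    for (i in which(keep)) {
      i0 <- floor(rest_events$onset_s[i] * fs) + 1
      i1 <- min(length(pc), i0 + round(rest_events$duration_s[i] * fs) - 1)
      seg <- pc[i0:i1]
      seg <- seg[!is.na(seg)]
      if (length(seg) > 1) vars <- c(vars, stats::var(seg))
    }
    if (length(vars)) rv <- mean(vars)
  }
  structure(list(diameter_um = diameter_um, percent_change = pc,
                 resting_variance = rv, n_invalid = sum(!valid)),
            class = "diameter_trace")
}
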