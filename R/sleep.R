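# Arousal-state scoring: per-5-s-bin features, bagged-forest classification,
# and segmentation of labeled sessions into analysis epochs.

#' Extract per-bin scoring features
#'
#' One row per 5-s bin: cortical delta/beta/gamma power, hippocampal theta
#' power (multitaper spectra per bin; cortical power averaged over
#' hemispheres), EMG log power (mean of the EMG envelope), heart rate (from
#' the isosbestic reflectance; missing bins filled by interpolation), and
#' whisking duration (seconds above an adaptive threshold).
#'
#' For speed the LFP channels are decimated to 250 Hz before the per-bin
#' spectra (all feature bands lie below 100 Hz).
#'
#' @param session a `recording_session`.
#' @param nw,k taper parameters for the per-bin spectra (default 3, 5).
#' @return data.frame of class `feature_table`, one row per complete bin.
#' @export
extract_features <- function(session, nw = 3, k = 5) {
  fs <- session$fs$neural
  fso <- session$fs$optical
  fs_spec <- 250
  n_bins <- floor(length(session$channels$emg) / fs / 5)
  dec <- function(x) resample_trace(x, fs, fs_spec)
  ctxL <- dec(session$channels$lfp_cortexL)
  ctxR <- dec(session$channels$lfp_cortexR)
  hipp <- dec(session$channels$lfp_hipp)
  bands <- list(delta = c(1, 4), beta = c(13, 30), gamma = c(30, 100))
  bpL <- batch_band_powers(ctxL, fs_spec, n_bins, bands, nw, k)
  bpR <- batch_band_powers(ctxR, fs_spec, n_bins, bands, nw, k)
  bpH <- batch_band_powers(hipp, fs_spec, n_bins, list(theta = c(4, 10)),
                           nw, k)
  delta <- (bpL$delta + bpR$delta) / 2
  beta <- (bpL$beta + bpR$beta) / 2
  gamma <- (bpL$gamma + bpR$gamma) / 2
  theta <- bpH$theta
  emg_env <- suppressWarnings(emg_envelope(session$channels$emg, fs))
  emg_pow <- bin_means(emg_env, 30, n_bins)
  hr_src <- session$channels$refl_530_L %||% session$channels$refl_530_R
  heart <- if (!is.null(hr_src)) {
    h <- heart_rate_estimate(hr_src, fso)[seq_len(n_bins)]
    fill_na(h)
  } else rep(NA_real_, n_bins)
  whisk <- whisking_duration(session$channels$whisker, fso, n_bins)
  structure(data.frame(delta = delta, beta = beta, gamma = gamma,
                       theta = theta, emg = emg_pow, heart_rate = heart,
                       whisk_s = whisk),
            class = c("feature_table", "data.frame"))
}

# per-bin multitaper band powers for all bins at once (chunked batched FFTs)
batch_band_powers <- function(x, fs, n_bins, bands, nw = 3, k = 5,
                              bin_s = 5, chunk = 2000L) {
  nb_s <- round(bin_s * fs)
  nfft <- stats::nextn(nb_s, 2)
  tapers <- dpss_tapers(nb_s, nw, k)
  half <- seq_len(nfft %/% 2 + 1)
  freqs <- (half - 1) * fs / nfft
  df <- fs / nfft
  scale2 <- rep(2, length(half)); scale2[1] <- 1
  if (nfft %% 2 == 0) scale2[length(half)] <- 1
  sel <- lapply(bands, function(b) which(freqs >= b[1] & freqs <= b[2]))
  out <- lapply(bands, function(b) numeric(n_bins))
  # linear-detrend projection applied column-wise
  tt <- seq_len(nb_s)
  B <- cbind(1, tt)
  P <- B %*% solve(crossprod(B), t(B))
  for (c0 in seq(1L, n_bins, by = chunk)) {
    c1 <- min(n_bins, c0 + chunk - 1L)
    idx <- ((c0 - 1) * nb_s + 1):(c1 * nb_s)
    m <- matrix(x[idx], nb_s, c1 - c0 + 1L)
    m <- m - P %*% m
    acc <- matrix(0, length(half), ncol(m))
    for (j in seq_len(k)) {
      F <- stats::mvfft(rbind(m * tapers[, j],
                              matrix(0, nfft - nb_s, ncol(m))))
      acc <- acc + Mod(F[half, , drop = FALSE])^2
    }
    acc <- acc * (scale2 / (k * fs))
    for (b in names(bands)) {
      out[[b]][c0:c1] <- colSums(acc[sel[[b]], , drop = FALSE]) * df
    }
  }
  out
}

bin_means <- function(x, fs, n_bins, bin_s = 5) {
  nb <- round(bin_s * fs)
  vapply(seq_len(n_bins), function(i) {
    mean(x[((i - 1) * nb + 1):min(length(x), i * nb)])
  }, numeric(1))
}

fill_na <- function(x) {
  if (all(is.na(x))) return(rep(0, length(x)))
  if (anyNA(x)) {
    ok <- which(!is.na(x))
    x <- stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
  }
  x
}

#' Adaptive whisking threshold
#'
#' 3 SD of the whisker-motion signal during quiescence, with the quiescent
#' set re-estimated once (two passes).
#'
#' @param whisker motion magnitude trace.
#' @return threshold on the same scale.
#' @export
whisking_threshold <- function(whisker) {
  thr <- 3 * stats::sd(whisker)
  for (i in 1:2) {
    quiet <- whisker < thr
    if (sum(quiet) < 10) break
    thr <- 3 * stats::sd(whisker[quiet])
  }
  thr
}

whisking_duration <- function(whisker, fs, n_bins, bin_s = 5) {
  if (is.null(whisker)) return(rep(0, n_bins))
  thr <- whisking_threshold(whisker)
  above <- whisker > thr
  nb <- round(bin_s * fs)
  vapply(seq_len(n_bins), function(i) {
    idx <- ((i - 1) * nb + 1):min(length(above), i * nb)
    sum(above[idx]) / fs
  }, numeric(1))
}

#' Train the arousal-state classifier
#'
#' Bagged decision forest over the scoring features with stratified
#' bootstrap; validation by out-of-bag error.
#'
#' @param features `feature_table` (or data.frame) of predictors.
#' @param labels per-bin state factor (Awake/NREM/REM).
#' @param n_trees forest size (default 128).
#' @param seed RNG seed.
#' @return `bagged_forest` (see [bagged_forest()]).
#' @export
train_classifier <- function(features, labels, n_trees = 128, seed = 1L) {
  bagged_forest(as.matrix(as.data.frame(features)), labels,
                n_trees = n_trees, seed = seed)
}

#' Score a session's bins
#'
#' @param model trained [bagged_forest()].
#' @param features `feature_table`.
#' @return factor of per-bin labels.
#' @export
score_bins <- function(model, features) {
  predict(model, as.matrix(as.data.frame(features)))
}

#' Segment labeled bins into analysis epochs
#'
#' Implements the epoch rules: a 15-min block is `Alert` when > 80% of its
#' bins are Awake and `Asleep` when > 80% are NREM or REM (otherwise
#' `Neither`); rest events are contiguous Awake bins >= 10 s with no whisker
#' or body motion; NREM events are contiguous runs >= 30 s; REM events
#' >= 60 s; transitions are 30 s of one state's consecutive classifications
#' followed immediately by 30 s of another.
#'
#' @param bin_labels per-bin factor (Awake/NREM/REM).
#' @param whisker,force optional motion traces at `fs_motion` for rest
#'   detection.
#' @param fs_motion sampling rate of the motion traces, Hz.
#' @param exclude_first_s exclude this initial span (the stimulation period)
#'   from blocks and events (default 0; set to 3600 to mirror the
#'   experimental protocol).
#' @param bin_s bin length, seconds (5).
#' @return object of class `arousal_labels`: `bin_labels`, `blocks`
#'   (data.frame per 15-min block), `rest_events`, `nrem_events`,
#'   `rem_events` (data.frames with `onset_s`, `duration_s`), `transitions`
#'   (data.frame with `time_s`, `from`, `to`).
#' @export
segment_periods <- function(bin_labels, whisker = NULL, force = NULL,
                            fs_motion = 30, exclude_first_s = 0, bin_s = 5) {
  n <- length(bin_labels)
  lab <- as.character(bin_labels)
  first_bin <- floor(exclude_first_s / bin_s) + 1
  usable <- seq_len(n) >= first_bin

  # 15-min blocks
  bpb <- round(900 / bin_s)
  n_blocks <- floor(n / bpb)
  blocks <- data.frame(block = seq_len(n_blocks),
                       onset_s = (seq_len(n_blocks) - 1) * 900,
                       state = character(n_blocks),
                       stringsAsFactors = FALSE)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1) * bpb + 1):(b * bpb)
    if (!all(usable[idx])) { blocks$state[b] <- "Excluded"; next }
    fa <- mean(lab[idx] == "Awake")
    fs_ <- mean(lab[idx] %in% c("NREM", "REM"))
    blocks$state[b] <- if (fa > 0.8) "Alert" else if (fs_ > 0.8) "Asleep" else "Neither"
  }

  # per-bin motion flag for rest detection
  moving <- rep(FALSE, n)
  flag_motion <- function(trace) {
    if (is.null(trace)) return(rep(FALSE, n))
    thr <- whisking_threshold(trace)
    nb <- round(bin_s * fs_motion)
    vapply(seq_len(n), function(i) {
      idx <- ((i - 1) * nb + 1):min(length(trace), i * nb)
      if (idx[1] > length(trace)) return(FALSE)
      any(trace[idx] > thr)
    }, logical(1))
  }
  moving <- flag_motion(whisker) | flag_motion(force)

  seg_df <- function(run_mat) {
    if (nrow(run_mat) == 0) {
      return(data.frame(onset_s = numeric(), duration_s = numeric()))
    }
    data.frame(onset_s = (run_mat[, "start"] - 1) * bin_s,
               duration_s = (run_mat[, "end"] - run_mat[, "start"] + 1) * bin_s)
  }
  min_bins <- function(mat, k) mat[mat[, "end"] - mat[, "start"] + 1 >= k, , drop = FALSE]

  rest <- seg_df(min_bins(runs_true(lab == "Awake" & !moving & usable), 2))
  nrem <- seg_df(min_bins(runs_true(lab == "NREM" & usable), 6))
  rem <- seg_df(min_bins(runs_true(lab == "REM" & usable), 12))

  # transitions: 6 pure bins of one state then 6 pure bins of another
  trans <- data.frame(time_s = numeric(), from = character(), to = character(),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n - 1)) {
    if (lab[i] == lab[i + 1]) next
    if (i < 6 || i + 6 > n) next
    if (!all(usable[(i - 5):(i + 6)])) next
    if (all(lab[(i - 5):i] == lab[i]) && all(lab[(i + 1):(i + 6)] == lab[i + 1])) {
      trans <- rbind(trans, data.frame(time_s = i * bin_s, from = lab[i],
                                       to = lab[i + 1]))
    }
  }
  structure(list(bin_labels = factor(lab, levels = state_levels),
                 blocks = blocks, rest_events = rest, nrem_events = nrem,
                 rem_events = rem, transitions = trans, bin_s = bin_s),
            class = "arousal_labels")
}

#' @export
print.arousal_labels <- function(x, ...) {
  cat("<arousal_labels>", length(x$bin_labels), "bins;",
      sum(x$blocks$state == "Alert"), "Alert /",
      sum(x$blocks$state == "Asleep"), "Asleep blocks;",
      nrow(x$rest_events), "rest,", nrow(x$nrem_events), "NREM,",
      nrow(x$rem_events), "REM events;", nrow(x$transitions), "transitions\n")
  invisible(x)
}
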