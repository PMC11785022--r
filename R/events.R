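# Event-triggered responses, neurovascular slope, state-conditioned
# summaries, bilateral comparisons, and transition dynamics.

#' Event-triggered average
#'
#' Extracts trials around event onsets, subtracts each trial's mean over the
#' 2 s preceding onset, smooths with a 3rd-order Savitzky-Golay filter, and
#' averages. Trials extending past either end of the trace are dropped and
#' counted.
#'
#' @param trace numeric trace.
#' @param onsets_s event onset times, seconds.
#' @param fs sampling rate, Hz.
#' @param pre_s,post_s window before/after onset, seconds (default 2 and 10).
#' @param windows named list of `c(t0, t1)` evaluation intervals (seconds
#'   after onset) for window statistics.
#' @param sg_window Savitzky-Golay window length in samples (default 17).
#' @return object of class `evoked_response`: `time_s`, `mean`, `sem`,
#'   `n_trials`, `n_dropped`, `window_stats` (data.frame name/t0/t1/mean).
#' @export
triggered_average <- function(trace, onsets_s, fs, pre_s = 2, post_s = 10,
                              windows = list(), sg_window = 17) {
  npre <- round(pre_s * fs); npost <- round(post_s * fs)
  trials <- list()
  dropped <- 0L
  for (on in onsets_s) {
    i0 <- round(on * fs) + 1
    idx <- (i0 - npre):(i0 + npost - 1)
    if (idx[1] < 1 || idx[length(idx)] > length(trace)) {
      dropped <- dropped + 1L
      next
    }
    tr <- trace[idx]
    tr <- tr - mean(tr[seq_len(npre)])
    trials[[length(trials) + 1]] <- savitzky_golay(tr, 3, sg_window)
  }
  if (!length(trials)) stop("no usable trials")
  m <- do.call(rbind, trials)
  avg <- colMeans(m)
  sem <- apply(m, 2, stats::sd) / sqrt(nrow(m))
  time_s <- (seq_len(npre + npost) - npre - 1) / fs
  ws <- data.frame(name = character(), t0 = numeric(), t1 = numeric(),
                   mean = numeric(), stringsAsFactors = FALSE)
  for (nm in names(windows)) {
    w <- windows[[nm]]
    sel <- time_s >= w[1] & time_s <= w[2]
    ws <- rbind(ws, data.frame(name = nm, t0 = w[1], t1 = w[2],
                               mean = mean(avg[sel])))
  }
  structure(list(time_s = time_s, mean = avg, sem = sem,
                 n_trials = nrow(m), n_dropped = dropped,
                 trials = m, window_stats = ws),
            class = "evoked_response")
}

#' Through-origin neurovascular slope
#'
#' Least-squares slope of blood volume against neural response with zero
#' intercept: `s = sum(x*y) / sum(x^2)`.
#'
#' @param neural per-trial (or per-animal) neural window means.
#' @param hemo matching blood-volume window means.
#' @return slope, or `NA` with a warning when the neural responses are all
#'   zero.
#' @export
neurovascular_slope <- function(neural, hemo) {
  if (length(neural) != length(hemo)) stop("paired inputs required")
  sx2 <- sum(neural^2)
  if (sx2 == 0) {
    warning("all-zero neural response; slope undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(neural * hemo) / sx2
}

event_segments <- function(trace, fs, events) {
  segs <- list()
  for (i in seq_len(nrow(events))) {
    i0 <- floor(events$onset_s[i] * fs) + 1
    i1 <- min(length(trace), i0 + round(events$duration_s[i] * fs) - 1)
    if (i0 >= 1 && i1 > i0) segs[[length(segs) + 1]] <- trace[i0:i1]
  }
  segs
}

#' State-conditioned hemodynamic summaries
#'
#' Per-event zero-phase lowpass (< 1 Hz, 4th order), then the per-event mean
#' (NREM/REM state means relative to the awake-rest baseline) or variance
#' (rest events); event-level values are averaged to one row per state.
#'
#' @param trace blood-volume trace (uM).
#' @param fs sampling rate, Hz.
#' @param labels [segment_periods()] output.
#' @return data.frame with columns `state`, `metric`, `value`, `n_events`:
#'   resting variance (uM^2), resting mean, NREM mean, REM mean (uM).
#' @export
state_summaries <- function(trace, fs, labels) {
  lp <- function(seg) if (length(seg) > 8) lowpass(seg, fs, 1, order = 4) else seg
  rows <- list()
  summarize <- function(events, state, metric, f) {
    if (is.null(events) || nrow(events) == 0) return()
    vals <- vapply(event_segments(trace, fs, events),
                   function(s) f(lp(s)), numeric(1))
    rows[[length(rows) + 1]] <<- data.frame(state = state, metric = metric,
                                            value = mean(vals),
                                            n_events = length(vals))
  }
  summarize(labels$rest_events, "Rest", "variance", stats::var)
  summarize(labels$rest_events, "Rest", "mean", mean)
  summarize(labels$nrem_events, "NREM", "mean", mean)
  summarize(labels$rem_events, "REM", "mean", mean)
  do.call(rbind, rows) %||% data.frame(state = character(),
                                       metric = character(),
                                       value = numeric(),
                                       n_events = integer())
}

#' Bilateral correlation and coherence per state
#'
#' Pearson correlation of the left and right traces per event (after mean
#' subtraction and < 1 Hz lowpass, the standard filtering convention),
#' averaged per state, plus the band-mean multitaper coherence across
#' events.
#'
#' @param left,right equal-length traces.
#' @param fs sampling rate, Hz.
#' @param events data.frame of events (`onset_s`, `duration_s`) to compare
#'   within (e.g. rest events or Alert blocks).
#' @param coh_band frequency band for the coherence summary, Hz.
#' @param nw,k taper parameters.
#' @param truncate_s use only the first `truncate_s` seconds of each event so
#'   all coherence segments share one length (default: shortest event).
#' @return list with `pearson_r` (mean per-event r), `coherence` (band-mean
#'   coherence), `spectrum` (the coherence `spectral_estimate`), `n_events`.
#' @export
bilateral_comparison <- function(left, right, fs, events,
                                 coh_band = c(0.1, 0.5), nw = 3, k = 5,
                                 truncate_s = NULL) {
  if (length(left) != length(right)) stop("traces must have equal length")
  if (nrow(events) == 0) stop("no events supplied")
  truncate_s <- truncate_s %||% min(events$duration_s)
  nseg <- round(truncate_s * fs)
  lf <- lowpass(left - mean(left), fs, 1, order = 4)
  rf <- lowpass(right - mean(right), fs, 1, order = 4)
  segsL <- list(); segsR <- list(); rs <- c()
  for (i in seq_len(nrow(events))) {
    i0 <- floor(events$onset_s[i] * fs) + 1
    i1 <- i0 + nseg - 1
    if (i1 > length(left)) next
    segsL[[length(segsL) + 1]] <- lf[i0:i1]
    segsR[[length(segsR) + 1]] <- rf[i0:i1]
    rs <- c(rs, stats::cor(lf[i0:i1], rf[i0:i1]))
  }
  if (!length(segsL)) stop("no usable events")
  coh <- multitaper_coherence(segsL, segsR, fs, nw = nw, k = k)
  list(pearson_r = mean(rs), coherence = band_mean(coh, coh_band),
       spectrum = coh, n_events = length(segsL))
}

#' Pre/post difference across arousal-state transitions
#'
#' On the < 1 Hz lowpassed trace, the mean over [+10, +30] s after each
#' transition minus the mean over [-30, -10] s before it. Transitions whose
#' windows extend outside the trace are dropped.
#'
#' @param trace numeric trace.
#' @param fs sampling rate, Hz.
#' @param transitions data.frame from [segment_periods()] (`time_s`, `from`,
#'   `to`).
#' @return data.frame `time_s`, `from`, `to`, `delta` (one row per usable
#'   transition).
#' @export
transition_delta <- function(trace, fs, transitions) {
  x <- lowpass(trace, fs, 1, order = 4)
  out <- list()
  for (i in seq_len(nrow(transitions))) {
    t0 <- transitions$time_s[i]
    pre <- round((t0 - 30) * fs):round((t0 - 10) * fs)
    post <- round((t0 + 10) * fs):round((t0 + 30) * fs)
    if (pre[1] < 1 || post[length(post)] > length(x)) next
    out[[length(out) + 1]] <- data.frame(
      time_s = t0, from = transitions$from[i], to = transitions$to[i],
      delta = mean(x[post]) - mean(x[pre]))
  }
  do.call(rbind, out) %||% data.frame(time_s = numeric(), from = character(),
                                      to = character(), delta = numeric())
}

#' Locomotion onset detection
#'
#' Threshold crossings of the body force sensor separated by at least
#' `min_quiet_s` of sub-threshold signal.
#'
#' @param force force-sensor trace.
#' @param fs sampling rate, Hz.
#' @param min_quiet_s required quiescence before an onset (default 5).
#' @param min_bout_s shortest supra-threshold run counted as locomotion
#'   (default 0.2 s; rejects isolated noise samples).
#' @return onset times, seconds.
#' @export
locomotion_onsets <- function(force, fs, min_quiet_s = 5, min_bout_s = 0.2) {
  thr <- whisking_threshold(force)
  above <- force > thr
  onsets <- c()
  last <- -Inf
  runs <- runs_true(above)
  runs <- runs[runs[, "end"] - runs[, "start"] + 1 >= min_bout_s * fs, ,
               drop = FALSE]
  for (i in seq_len(nrow(runs))) {
    t_on <- (runs[i, "start"] - 1) / fs
    if (t_on - last >= min_quiet_s) onsets <- c(onsets, unname(t_on))
    last <- (runs[i, "end"] - 1) / fs
  }
  onsets
}
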