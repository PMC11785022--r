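# Plain-text session store. A session directory holds:
#   neural.csv   - electrophysiology channels at fs_neural
#   optical.csv  - reflectance/fluorescence/behavior channels at fs_optical
#   events.csv   - event log (onset_s, type, duration_s, side)
#   truth.csv    - ground-truth traces (synthetic sessions only)
#   states.csv   - ground-truth per-bin labels (synthetic sessions only)
#   meta.json    - sampling rates and generator parameters
# (An HDF5 layout would be preferred for real data volumes; no HDF5 binding
# is available in this toolchain, so the store is columnar text.)

#' Write a session to a directory
#'
#' @param session `recording_session`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ch <- session$channels
  neural_names <- intersect(c("lfp_cortexL", "lfp_cortexR", "lfp_hipp", "emg"),
                            names(ch))
  optical_names <- setdiff(names(ch), neural_names)
  utils::write.csv(as.data.frame(ch[neural_names]),
                   file.path(dir, "neural.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(ch[optical_names]),
                   file.path(dir, "optical.csv"), row.names = FALSE)
  utils::write.csv(session$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  if (!is.null(session$truth)) {
    tr <- session$truth
    truth_df <- data.frame(
      dHbT_L = tr$dHbT[, 1], dHbT_R = tr$dHbT[, 2],
      dHbO_L = tr$dHbO[, 1], dHbO_R = tr$dHbO[, 2],
      dHbR_L = tr$dHbR[, 1], dHbR_R = tr$dHbR[, 2],
      diameter_um_L = tr$diameter_um[, 1],
      diameter_um_R = tr$diameter_um[, 2],
      gamma_env_L = tr$gamma_envelope[, 1],
      gamma_env_R = tr$gamma_envelope[, 2])
    if (!is.null(tr$dff_true)) {
      truth_df$dff_true_L <- tr$dff_true[, 1]
      truth_df$dff_true_R <- tr$dff_true[, 2]
    }
    utils::write.csv(truth_df, file.path(dir, "truth.csv"), row.names = FALSE)
    utils::write.csv(data.frame(state = as.character(tr$states)),
                     file.path(dir, "states.csv"), row.names = FALSE)
    kernel <- tr$true_kernel
  } else kernel <- NULL
  meta <- list(fs = session$fs,
               true_kernel = kernel,
               params = serialize_params(session$truth$params %||% NULL))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

serialize_params <- function(p) {
  if (is.null(p)) return(NULL)
  p <- unclass(p)
  p$state_transition_matrix <- as.data.frame(p$state_transition_matrix)
  p$band_power_by_state <- as.data.frame(p$band_power_by_state)
  p
}

deserialize_params <- function(p) {
  if (is.null(p) || !length(p)) return(NULL)
  m <- as.matrix(as.data.frame(p$state_transition_matrix))
  dimnames(m) <- list(state_levels, state_levels)
  bp <- as.matrix(as.data.frame(p$band_power_by_state))
  dimnames(bp) <- list(c("delta", "beta", "gamma", "theta"), state_levels)
  st <- p$stim_times
  if (!is.null(st)) st <- as.data.frame(st)
  gen_params(state_transition_matrix = m, band_power_by_state = bp,
             emg_power_by_state = unlist(p$emg_power_by_state),
             hrf_true = p$hrf_true,
             undershoot_gain = p$undershoot_gain,
             vasomotion_sigma = p$vasomotion_sigma,
             bilateral_shared_fraction = p$bilateral_shared_fraction,
             state_hbt_offset_uM = unlist(p$state_hbt_offset_uM),
             evoked_amp_uM = p$evoked_amp_uM,
             brief_peak_uM = p$brief_peak_uM,
             undershoot_uM = p$undershoot_uM,
             oxy_ratio = p$oxy_ratio,
             heart_rate_by_state = unlist(p$heart_rate_by_state),
             heart_pulse_amp = p$heart_pulse_amp,
             baseline_diameter_um = p$baseline_diameter_um,
             diameter_percent_per_uM = p$diameter_percent_per_uM,
             stim_times = st, stim_period_s = p$stim_period_s,
             stim_gamma_gain = p$stim_gamma_gain,
             fs_neural = p$fs_neural, fs_optical = p$fs_optical,
             seed = p$seed)
}

#' Read a session directory
#'
#' @param dir directory written by [write_session()].
#' @return `recording_session`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  neural <- utils::read.csv(file.path(dir, "neural.csv"))
  optical <- utils::read.csv(file.path(dir, "optical.csv"))
  events <- utils::read.csv(file.path(dir, "events.csv"))
  channels <- c(as.list(neural), as.list(optical))
  truth <- NULL
  tf <- file.path(dir, "truth.csv")
  if (file.exists(tf)) {
    td <- utils::read.csv(tf)
    states <- factor(utils::read.csv(file.path(dir, "states.csv"))$state,
                     levels = state_levels)
    truth <- list(
      states = states,
      dHbT = cbind(L = td$dHbT_L, R = td$dHbT_R),
      dHbO = cbind(L = td$dHbO_L, R = td$dHbO_R),
      dHbR = cbind(L = td$dHbR_L, R = td$dHbR_R),
      diameter_um = cbind(L = td$diameter_um_L, R = td$diameter_um_R),
      gamma_envelope = cbind(td$gamma_env_L, td$gamma_env_R),
      true_kernel = unlist(meta$true_kernel),
      params = deserialize_params(meta$params))
    if (!is.null(td$dff_true_L)) {
      truth$dff_true <- cbind(td$dff_true_L, td$dff_true_R)
    }
  }
  structure(list(channels = channels, fs = meta$fs, events = events,
                 truth = truth),
            class = "recording_session")
}
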