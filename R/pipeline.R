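# End-to-end analysis driver and command-line entry points.

#' Run the analysis chain on a session
#'
#' Applies the requested stages to a session: hemoglobin spectroscopy
#' (reflectance -> concentrations, fluorescence correction), arousal scoring
#' (features + forest trained on ground-truth labels when available),
#' evoked responses, bilateral coherence, and HRF estimation. Returns a
#' named list of per-stage results; `summary` collects one row per metric
#' for export.
#'
#' @param session `recording_session`.
#' @param stages character vector among `"spectroscopy"`, `"scoring"`,
#'   `"evoked"`, `"coherence"`, `"hrf"`.
#' @param constants [spectroscopy_constants()].
#' @param exclude_first_s initial span excluded from state analyses
#'   (default: the stimulation period when events are present, else 0).
#' @param seed RNG seed for the classifier.
#' @return list of stage results plus `summary` data.frame.
#' @export
analyze_session <- function(session,
                            stages = c("spectroscopy", "scoring", "evoked",
                                       "coherence", "hrf"),
                            constants = spectroscopy_constants(),
                            exclude_first_s = NULL, seed = 1L) {
  out <- list()
  fso <- session$fs$optical
  exclude_first_s <- exclude_first_s %||%
    if (nrow(session$events)) min(3600, max(session$events$onset_s + 30)) else 0

  if ("scoring" %in% stages) {
    feats <- extract_features(session)
    truth_states <- session$truth$states
    model <- train_classifier(feats, truth_states, seed = seed)
    labels_hat <- score_bins(model, feats)
    out$scoring <- list(features = feats, model = model,
                        bin_labels = labels_hat,
                        accuracy = mean(as.character(labels_hat) ==
                                          as.character(truth_states)))
    lab_src <- labels_hat
  } else {
    lab_src <- session$truth$states
  }
  out$labels <- segment_periods(lab_src, session$channels$whisker,
                                session$channels$force, fs_motion = fso,
                                exclude_first_s = exclude_first_s)

  if ("spectroscopy" %in% stages) {
    # awake-rest baseline: mean reflectance over detected rest events
    base_idx <- rest_sample_index(out$labels$rest_events, fso,
                                  length(session$channels[[
                                    paste0("refl_",
                                           constants$wavelengths_nm[1], "_L")]]))
    out$hemo <- session_spectroscopy(session, constants,
                                     baseline_idx = base_idx)
  }
  hbt <- if (!is.null(out$hemo$L)) out$hemo$L$dHbT else session$truth$dHbT[, 1]
  hbt_r <- if (!is.null(out$hemo$R)) out$hemo$R$dHbT else session$truth$dHbT[, 2]

  if ("evoked" %in% stages && nrow(session$events)) {
    contra <- session$events[session$events$type != "auditory", ]
    brief <- contra[contra$duration_s < 1, ]
    long <- contra[contra$duration_s >= 1, ]
    if (nrow(brief)) {
      out$evoked_brief <- triggered_average(
        hbt, brief$onset_s, fso,
        windows = list(undershoot = c(2, 4)))
    }
    if (nrow(long)) {
      out$evoked_long <- triggered_average(
        hbt, long$onset_s, fso,
        windows = list(sustained = c(1.5, 6.5)))
    }
  }

  if ("coherence" %in% stages && nrow(out$labels$rest_events)) {
    out$bilateral_rest <- bilateral_comparison(
      hbt, hbt_r, fso, out$labels$rest_events, coh_band = c(0.1, 0.5),
      truncate_s = 10)
  }

  if ("hrf" %in% stages) {
    env <- session$truth$gamma_envelope[, 1]
    out$hrf <- fit_hrf(env, hbt, fs = fso)
  }

  out$summary <- build_summary(out, hbt, fso)
  out
}

rest_sample_index <- function(rest_events, fs, n) {
  if (is.null(rest_events) || nrow(rest_events) == 0) return(seq_len(n))
  idx <- unlist(lapply(seq_len(nrow(rest_events)), function(i) {
    i0 <- floor(rest_events$onset_s[i] * fs) + 1
    i0:min(n, i0 + round(rest_events$duration_s[i] * fs) - 1)
  }))
  idx[idx >= 1 & idx <= n]
}

session_spectroscopy <- function(session, constants, baseline_idx = NULL) {
  res <- list()
  for (hemi in c("L", "R")) {
    nm <- paste0("refl_", constants$wavelengths_nm, "_", hemi)
    if (!all(nm %in% names(session$channels))) next
    I <- do.call(cbind, session$channels[nm])
    bi <- baseline_idx %||% seq_len(nrow(I))
    I0 <- colMeans(I[bi, , drop = FALSE])
    dA <- delta_absorbance(I, I0)
    res[[hemi]] <- invert_beer_lambert(dA, constants)
    fl <- session$channels[[paste0("fluor_", hemi)]]
    if (!is.null(fl)) {
      g <- session$channels[[paste0(
        "refl_", constants$wavelengths_nm[constants$isosbestic_index], "_",
        hemi)]]
      res[[hemi]]$dFF_corrected <- correct_fluorescence(fl, g, mean(g[bi]),
                                                        baseline_idx = bi)
    }
  }
  res
}

build_summary <- function(out, hbt, fso) {
  rows <- list()
  add <- function(metric, value) {
    rows[[length(rows) + 1]] <<- data.frame(metric = metric, value = value)
  }
  if (!is.null(out$labels)) {
    ss <- state_summaries(hbt, fso, out$labels)
    for (i in seq_len(nrow(ss))) {
      add(paste0(tolower(ss$state[i]), "_", ss$metric[i]), ss$value[i])
    }
  }
  if (!is.null(out$evoked_brief)) {
    add("brief_undershoot_2_4s", out$evoked_brief$window_stats$mean[1])
  }
  if (!is.null(out$evoked_long)) {
    add("long_sustained_1.5_6.5s", out$evoked_long$window_stats$mean[1])
  }
  if (!is.null(out$bilateral_rest)) {
    add("bilateral_rest_r", out$bilateral_rest$pearson_r)
    add("bilateral_rest_coherence", out$bilateral_rest$coherence)
  }
  if (!is.null(out$scoring)) add("scoring_accuracy", out$scoring$accuracy)
  if (!is.null(out$hrf)) {
    add("hrf_t_peak", out$hrf$gamma_params$t_peak)
    add("hrf_r_squared", out$hrf$r_squared)
  }
  do.call(rbind, rows) %||% data.frame(metric = character(), value = numeric())
}

#' Command-line interface
#'
#' Entry point used by the `nvc` script (`inst/cli/nvc`):
#' `nvc generate --out DIR [--config FILE] [--seed N] [--duration S]`,
#' `nvc score DIR`, and
#' `nvc analyze DIR [--stages a,b,c] [--out DIR]`.
#'
#' @param args command-line arguments (default `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
nvc_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: nvc <generate|score|analyze> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  seed <- as.integer(opts$seed %||% 1)
  if (cmd == "generate") {
    params <- if (!is.null(opts$config)) {
      cfg <- yaml::read_yaml(opts$config)
      do.call(gen_params, c(cfg, list(seed = seed)))
    } else gen_params(seed = seed)
    ses <- simulate_session(params,
                            duration_s = as.numeric(opts$duration %||% 1800))
    write_session(ses, opts$out %||% "session_out")
    cat("wrote session to", opts$out %||% "session_out", "\n")
  } else if (cmd == "score") {
    ses <- read_session(opts$dir %||% args[2])
    feats <- extract_features(ses)
    model <- train_classifier(feats, ses$truth$states, seed = seed)
    labs <- score_bins(model, feats)
    cat(sprintf("OOB error %.3f; accuracy vs truth %.3f\n", model$oob_error,
                mean(as.character(labs) == as.character(ses$truth$states))))
  } else if (cmd == "analyze") {
    ses <- read_session(opts$dir %||% args[2])
    stages <- strsplit(opts$stages %||%
                         "spectroscopy,scoring,evoked,coherence,hrf", ",")[[1]]
    res <- analyze_session(ses, stages = stages, seed = seed)
    print(res$summary)
    if (!is.null(opts$out)) {
      dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(res$summary, file.path(opts$out, "summary.csv"),
                       row.names = FALSE)
    }
  } else {
    cat("unknown command:", cmd, "\n")
    return(invisible(1L))
  }
  invisible(0L)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      opts[[substring(a, 3)]] <- if (i < length(args)) args[i + 1] else TRUE
      i <- i + 2
    } else {
      opts$dir <- a
      i <- i + 1
    }
  }
  opts
}
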