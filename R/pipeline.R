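# End-to-end runners: configuration, the task-EEG extraction pipeline
# (preprocess -> epoch -> label -> reject -> ERSP -> peak matrix -> ITF),
# the resting-state control analysis, and JSON/TSV report writers.

#' Default run configuration
#'
#' All analysis settings in one list: preprocessing, epoching, analysis
#' windows, electrodes, fallback, and bands.  The defaults reproduce the
#' reference settings of the method (0.1 Hz high-pass, 50 Hz line removal,
#' -1000..2500 ms epochs with a -800..0 ms baseline, 150 uV rejection,
#' 19 windows of 100 ms in 50 ms steps over 250-1250 ms, electrodes Cz, C3,
#' C4, Pz, P3, P4 with PO7/PO8 fallback below 20% theta share).
#'
#' @param ... named overrides of any top-level entry.
#' @return A config list of class `itfx_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    preprocess = list(highpass_hz = 0.1, line_freq_hz = 50,
                      reject_ptp_uv = 150, excluded_channels = character()),
    epoch = list(t0_ms = -1000, t1_ms = 2500, baseline_ms = c(-800, 0)),
    tfr = list(freq_min_hz = 1, freq_max_hz = 15, freq_step_hz = 0.5,
               n_cycles = 7, analysis_min_hz = 2, trial_norm = "average"),
    windows = list(start_ms = 250, end_ms = 1250, width_ms = 100, step_ms = 50),
    electrodes = c("Cz", "C3", "C4", "Pz", "P3", "P4"),
    fallback = list(electrodes = c("PO7", "PO8"), trigger_theta_share_pct = 20),
    bands = list(delta = c(2, 4), theta = c(4, 8), alpha = c(8, 12)),
    resting = list(epoch_ms = 3500, baseline_first_ms = 1000),
    window_stat = "mean",
    min_epochs_warn = 14
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "itfx_config")
}

#' Read a run configuration from YAML
#'
#' Unspecified entries fall back to [default_config()].
#'
#' @param path YAML file.
#' @return An `itfx_config` with a `paths` element when present in the file.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(default_config, y[names(y) != "paths"])
  cfg$paths <- y$paths
  cfg
}

cfg_windows <- function(cfg) do.call(make_time_windows, cfg$windows)
cfg_bands <- function(cfg) do.call(band_scheme, cfg$bands)
cfg_freqs <- function(cfg) seq(cfg$tfr$freq_min_hz, cfg$tfr$freq_max_hz,
                               by = cfg$tfr$freq_step_hz)

#' Run the full ITF extraction pipeline
#'
#' Order of operations: channel exclusion and high-pass filtering, line-noise
#' removal, epoching around encoding onsets with baseline correction,
#' subsequent-memory labeling, peak-to-peak epoch rejection, Morlet
#' decomposition of the successful epochs on the analysis electrodes (plus
#' the fallback electrodes so a triggered fallback needs no recomputation),
#' baseline-ratio ERSP, peak matrix, and modal theta extraction with
#' fallback.
#'
#' @param recording an [eeg_recording()] (or path to EDF/fixture).
#' @param events event table or TSV path.
#' @param behavior behavior table or TSV path.
#' @param config an [default_config()] list.
#' @param out_dir when given, the JSON report, the peak-matrix TSV and the
#'   run log are written there.
#' @return An `itf_report` list: the `itf_result` fields plus epoch counts,
#'   behavioral summary, config echo, and package version.
#' @export
run_extract <- function(recording, events, behavior,
                        config = default_config(), out_dir = NULL) {
  if (is.character(recording)) recording <- read_recording(recording)
  if (is.character(events)) events <- read_events(events)
  if (is.character(behavior)) behavior <- read_behavior(behavior)

  pp <- do.call(preprocess_config, config$preprocess)
  recording <- preprocess(recording, pp)

  enc <- events[events$block == "encoding", , drop = FALSE]
  eps <- epoch(recording, enc, t0_ms = config$epoch$t0_ms,
               t1_ms = config$epoch$t1_ms, baseline_ms = config$epoch$baseline_ms)
  labels <- label_epochs(events, behavior)
  eps <- apply_labels(eps, labels)
  n_rejected_bounds <- sum(eps$labels == "rejected")
  eps <- reject_epochs(eps, pp$reject_ptp_uv)

  keep <- trials_with_label(eps, "successful")
  n_successful <- sum(labels$label == "successful")
  if (length(keep) == 0)
    stop_itfx("no successful epochs available for ITF extraction",
              class = "itfx_data_error")
  if (length(keep) < config$min_epochs_warn)
    warning("only ", length(keep), " successful epochs retained (fewer than ",
            config$min_epochs_warn, "); the ITF estimate may be unstable",
            call. = FALSE)

  # The fallback electrodes are decomposed lazily: only when the primary
  # matrix actually triggers the fallback.
  ersp_for <- function(channels) {
    tfr <- morlet_power(eps, freqs_hz = cfg_freqs(config),
                        n_cycles = config$tfr$n_cycles,
                        channels = channels, trials = keep)
    ersp(tfr, baseline_ms = config$epoch$baseline_ms,
         analysis_freqs = c(config$tfr$analysis_min_hz, config$tfr$freq_max_hz),
         trial_norm = config$tfr$trial_norm)
  }
  em <- ersp_for(config$electrodes)
  pm <- peak_matrix(em, windows = cfg_windows(config),
                    electrodes = config$electrodes,
                    window_stat = config$window_stat)
  res <- extract_itf(pm, cfg_bands(config))
  if (res$band_shares["theta"] < config$fallback$trigger_theta_share_pct &&
      config$fallback$trigger_theta_share_pct > 0) {
    fb <- config$fallback$electrodes
    missing <- setdiff(fb, recording$channel_labels)
    if (length(missing)) {
      warning("fallback electrodes absent (", paste(missing, collapse = ", "),
              "); returning the primary extraction", call. = FALSE)
    } else {
      em <- combine_ersp(em, ersp_for(fb))
      pm <- peak_matrix(em, windows = cfg_windows(config),
                        electrodes = c(config$electrodes, fb),
                        window_stat = config$window_stat)
      res <- extract_itf(pm, cfg_bands(config))
      res$fallback_used <- TRUE
    }
  }
  attr(res, "peak_matrix") <- pm

  report <- c(unclass(res),
              list(n_epochs_used = length(keep),
                   n_epochs_rejected = sum(eps$labels == "rejected"),
                   n_epochs_rejected_bounds = n_rejected_bounds,
                   n_successful_labeled = n_successful,
                   n_encoding_trials = nrow(enc),
                   behavior = summarize_behavior(behavior),
                   config = unclass(config),
                   log = eps$log,
                   package_version = as.character(utils::packageVersion("itfx"))))
  class(report) <- c("itf_report", "itf_result")
  attr(report, "peak_matrix") <- attr(res, "peak_matrix")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Run the resting-state control analysis
#'
#' Preprocesses the resting recording, segments it into successive 3500 ms
#' pseudo-epochs (first 1000 ms as baseline), and applies the identical
#' ERSP / peak-matrix / extraction machinery.  When a task report is
#' supplied, the theta-share difference for this subject is included.
#'
#' @param recording resting [eeg_recording()] (or path).
#' @param config an [default_config()] list.
#' @param am_report optional `itf_report` from [run_extract()] on the same
#'   subject's task EEG.
#' @param out_dir optional output directory for the JSON report.
#' @return An `itf_report` for the control condition with element
#'   `condition = "resting"`.
#' @export
run_control <- function(recording, config = default_config(),
                        am_report = NULL, out_dir = NULL) {
  if (is.character(recording)) recording <- read_recording(recording)
  pp <- do.call(preprocess_config, config$preprocess)
  recording <- preprocess(recording, pp)
  eps <- segment_resting(recording, epoch_ms = config$resting$epoch_ms,
                         baseline_first_ms = config$resting$baseline_first_ms,
                         baseline_ms = config$epoch$baseline_ms)
  eps <- reject_epochs(eps, pp$reject_ptp_uv)
  keep <- trials_with_label(eps, "successful")

  use_elec <- unique(c(config$electrodes,
                       intersect(config$fallback$electrodes,
                                 recording$channel_labels)))
  tfr <- morlet_power(eps, freqs_hz = cfg_freqs(config),
                      n_cycles = config$tfr$n_cycles,
                      channels = use_elec, trials = keep)
  em <- ersp(tfr, baseline_ms = config$epoch$baseline_ms,
             analysis_freqs = c(config$tfr$analysis_min_hz, config$tfr$freq_max_hz),
             trial_norm = config$tfr$trial_norm)
  pm <- peak_matrix(em, windows = cfg_windows(config),
                    electrodes = config$electrodes,
                    window_stat = config$window_stat)
  res <- extract_itf(pm, cfg_bands(config))

  report <- c(unclass(res),
              list(condition = "resting",
                   n_epochs_used = length(keep),
                   n_epochs_rejected = sum(eps$labels == "rejected"),
                   config = unclass(config), log = eps$log,
                   package_version = as.character(utils::packageVersion("itfx"))))
  if (!is.null(am_report))
    report$theta_share_task_minus_rest <-
      unname(am_report$band_shares["theta"] - res$band_shares["theta"])
  class(report) <- c("itf_report", "itf_result")
  attr(report, "peak_matrix") <- pm
  if (!is.null(out_dir)) write_report(report, out_dir, prefix = "control")
  report
}

#' Write an extraction report to disk
#'
#' Writes `<prefix>_report.json`, `<prefix>_peak_matrix.tsv`, and
#' `<prefix>_log.txt` under `out_dir`.
#'
#' @param report an `itf_report`.
#' @param out_dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Path of the JSON report, invisibly.
#' @export
write_report <- function(report, out_dir, prefix = "itf") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- unclass(report)
  obj$band_shares <- as.list(obj$band_shares)
  json_path <- file.path(out_dir, paste0(prefix, "_report.json"))
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  pm <- attr(report, "peak_matrix")
  if (!is.null(pm))
    write_peak_matrix_tsv(pm, file.path(out_dir, paste0(prefix, "_peak_matrix.tsv")))
  if (length(report$log))
    writeLines(report$log, file.path(out_dir, paste0(prefix, "_log.txt")))
  invisible(json_path)
}
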