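# Epoching of continuous recordings around stimulus onsets, time-domain
# baseline correction, and resting-state segmentation.
#
# Time convention: milliseconds relative to stimulus onset; intervals are
# half-open [a, b) when converted to samples, with the onset sample counted
# on the post-stimulus side.  Millisecond-to-sample conversion rounds half
# away from zero (see round_half_away) so results are platform-reproducible.

#' Cut epochs around stimulus onsets
#'
#' Cuts `[t0_ms, t1_ms)` epochs around each onset and subtracts, per trial and
#' channel, the mean over the pre-stimulus baseline interval (time-domain DC
#' correction).  Epochs that do not fit inside the recording are kept in the
#' set with label `"rejected"` and all-NA data, and noted in the log.
#'
#' @param recording an [eeg_recording()].
#' @param events event table, or any data frame with an `onset_ms` column
#'   (`trial_id`/`pair_id` are carried along when present).
#' @param t0_ms,t1_ms epoch limits relative to onset (default -1000..2500 ms).
#' @param baseline_ms two-element vector, the baseline interval (default
#'   -800..0 ms) whose per-channel mean is subtracted.
#' @return An `eeg_epochs` object: `data` (trials x channels x samples),
#'   `fs`, `times_ms`, `labels` (all `"unlabeled"` initially, `"rejected"`
#'   for out-of-bounds trials), `channel_labels`, `trial_info`, `log`.
#' @export
epoch <- function(recording, events, t0_ms = -1000, t1_ms = 2500,
                  baseline_ms = c(-800, 0)) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (t1_ms <= t0_ms)
    stop_itfx("t1_ms must exceed t0_ms", class = "itfx_parameter_error")
  fs <- recording$fs
  onsets <- events$onset_ms
  if (is.null(onsets))
    stop_itfx("events must contain an onset_ms column", class = "itfx_data_error")

  n_samp <- as.integer(round_half_away((t1_ms - t0_ms) * fs / 1000))
  off0 <- as.integer(ms_to_samples(t0_ms, fs))
  offsets <- off0 + seq_len(n_samp) - 1L
  times_ms <- offsets / fs * 1000

  n_trials <- length(onsets)
  n_chan <- nrow(recording$data)
  data <- array(NA_real_, dim = c(n_trials, n_chan, n_samp))
  labels <- rep("unlabeled", n_trials)
  log <- character()
  total <- ncol(recording$data)
  for (i in seq_len(n_trials)) {
    i0 <- as.integer(ms_to_samples(onsets[i], fs)) + 1L  # onset sample, 1-based
    idx <- i0 + offsets
    if (idx[1] < 1L || idx[n_samp] > total) {
      labels[i] <- "rejected"
      log <- c(log, sprintf("trial %d rejected: epoch [%g, %g) ms around onset %g ms exceeds recording bounds",
                            i, t0_ms, t1_ms, onsets[i]))
      next
    }
    data[i, , ] <- recording$data[, idx, drop = FALSE]
  }

  ep <- structure(list(data = data, fs = fs, times_ms = times_ms,
                       t0_ms = t0_ms, t1_ms = t1_ms, baseline_ms = baseline_ms,
                       labels = labels,
                       channel_labels = recording$channel_labels,
                       trial_info = data.frame(
                         trial_id = events$trial_id %||% paste0("T", seq_len(n_trials)),
                         pair_id = events$pair_id %||% NA_character_,
                         onset_ms = onsets, stringsAsFactors = FALSE),
                       log = log),
                  class = "eeg_epochs")
  baseline_correct(ep)
}

#' Subtract the per-trial, per-channel baseline mean
#'
#' Idempotent time-domain DC correction over `baseline_ms` (half-open).
#'
#' @param epochs an `eeg_epochs` object.
#' @return The corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs) {
  b <- epochs$baseline_ms
  sel <- epochs$times_ms >= b[1] & epochs$times_ms < b[2]
  if (!any(sel))
    stop_itfx("baseline interval contains no samples", class = "itfx_parameter_error")
  mu <- rowMeans(epochs$data[, , sel, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - as.vector(mu)  # recycles over samples (dim 3)
  epochs
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples [%g, %g) ms @ %g Hz\n",
              d[1], d[2], d[3], x$t0_ms, x$t1_ms, x$fs))
  print(table(x$labels))
  invisible(x)
}

#' Segment a resting-state recording into pseudo-trials
#'
#' Splits the recording into consecutive non-overlapping epochs of
#' `epoch_ms` (default 3500 ms) whose first `baseline_first_ms` (default
#' 1000 ms) serve as the pre-stimulus period: the pseudo-onset is placed at
#' the end of that first second, so the downstream analysis windows
#' (250-1250 ms post-onset) apply unchanged.  The trailing remainder is
#' discarded.
#'
#' @param recording an [eeg_recording()].
#' @param epoch_ms pseudo-epoch length in ms.
#' @param baseline_first_ms length of the leading baseline segment in ms.
#' @param baseline_ms baseline-correction interval relative to the
#'   pseudo-onset (default -800..0 ms).
#' @return An `eeg_epochs` object with all labels set to `"successful"` so
#'   the standard extraction runs on every control epoch.
#' @export
segment_resting <- function(recording, epoch_ms = 3500, baseline_first_ms = 1000,
                            baseline_ms = c(-800, 0)) {
  stopifnot(inherits(recording, "eeg_recording"))
  dur <- recording_duration_ms(recording)
  n_ep <- floor(dur / epoch_ms)
  if (n_ep < 1)
    stop_itfx(sprintf("recording (%.0f ms) shorter than one %g ms epoch",
                      dur, epoch_ms), class = "itfx_data_error")
  onsets <- (seq_len(n_ep) - 1) * epoch_ms + baseline_first_ms
  ev <- data.frame(onset_ms = onsets,
                   trial_id = sprintf("REST%03d", seq_len(n_ep)),
                   pair_id = NA_character_)
  ep <- epoch(recording, ev, t0_ms = -baseline_first_ms,
              t1_ms = epoch_ms - baseline_first_ms, baseline_ms = baseline_ms)
  ep$labels[ep$labels == "unlabeled"] <- "successful"
  ep
}

#' Retained-trial indices
#'
#' @param epochs an `eeg_epochs`.
#' @param labels labels to keep.
#' @return integer indices of trials with one of `labels`.
#' @export
trials_with_label <- function(epochs, labels = "successful") {
  which(epochs$labels %in% labels)
}

#' Apply subsequent-memory labels to an epoch set
#'
#' Transfers labels from [label_epochs()] onto the epoch set by `pair_id`,
#' leaving `"rejected"` trials untouched.
#'
#' @param epochs an `eeg_epochs` built from encoding events.
#' @param labels data frame from [label_epochs()].
#' @return The relabeled `eeg_epochs`.
#' @export
apply_labels <- function(epochs, labels) {
  idx <- match(epochs$trial_info$pair_id, labels$pair_id)
  new <- labels$label[idx]
  keep <- epochs$labels != "rejected" & !is.na(new)
  epochs$labels[keep] <- new[keep]
  epochs
}
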