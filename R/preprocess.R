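# Continuous-signal conditioning: zero-phase high-pass filtering, line-noise
# removal, and an automated peak-to-peak epoch-rejection criterion standing in
# for manual artifact inspection.

#' Preprocessing configuration
#'
#' @param highpass_hz high-pass cutoff in Hz (default 0.1).
#' @param line_freq_hz power-line frequency, 50 or 60 Hz.
#' @param reject_ptp_uv peak-to-peak epoch-rejection threshold in microvolts.
#' @param excluded_channels channel labels to drop before analysis.
#' @return A validated list of class `preprocess_config`.
#' @export
preprocess_config <- function(highpass_hz = 0.1, line_freq_hz = 50,
                              reject_ptp_uv = 150, excluded_channels = character()) {
  if (!is_scalar_num(highpass_hz) || highpass_hz <= 0)
    stop_itfx("highpass_hz must be > 0", class = "itfx_parameter_error")
  if (!line_freq_hz %in% c(50, 60))
    stop_itfx("line_freq_hz must be 50 or 60", class = "itfx_parameter_error")
  if (!is_scalar_num(reject_ptp_uv) || reject_ptp_uv <= 0)
    stop_itfx("reject_ptp_uv must be > 0", class = "itfx_parameter_error")
  structure(list(highpass_hz = highpass_hz, line_freq_hz = line_freq_hz,
                 reject_ptp_uv = reject_ptp_uv,
                 excluded_channels = as.character(excluded_channels)),
            class = "preprocess_config")
}

# Zero-phase filter a channels x samples matrix with reflection padding.
# filtfilt() starts from zero initial conditions, so without padding a slow
# high-pass leaves a long edge transient; reflecting ~5 time constants of
# signal at each end pushes the transient outside the returned segment.
filtfilt_padded <- function(b, a, data, pad) {
  n <- ncol(data)
  pad <- min(pad, n - 1L)
  t(apply(data, 1L, function(x) {
    xp <- c(x[seq(pad + 1L, 2L)], x, x[seq(n - 1L, n - pad)])
    signal::filtfilt(b, a, xp)[pad + seq_len(n)]
  }))
}

#' Zero-phase high-pass filter
#'
#' Second-order Butterworth applied forward and backward
#' (`signal::filtfilt`), with reflection padding so slow edge transients do
#' not leak into the data.  The DC component is removed exactly
#' (the transfer function is zero at 0 Hz).
#'
#' @param recording an [eeg_recording()].
#' @param cutoff_hz cutoff frequency in Hz; must be below Nyquist.
#' @param order Butterworth order of each pass.
#' @return The filtered [eeg_recording()].
#' @export
highpass <- function(recording, cutoff_hz = 0.1, order = 2) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (cutoff_hz >= fs / 2)
    stop_itfx("cutoff must be below the Nyquist frequency ", fs / 2, " Hz",
              class = "itfx_parameter_error")
  bt <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  pad <- as.integer(ceiling(12 / (2 * pi * cutoff_hz) * fs))
  recording$data <- filtfilt_padded(bt$b, bt$a, recording$data, pad)
  recording
}

# RBJ-style biquad notch: numerator zero exactly at f0, -3 dB width bw_hz.
notch_coefficients <- function(f0, fs, bw_hz) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) * sinh(log(2) / 2 * (bw_hz / f0) * w0 / sin(w0))
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Remove power-line noise
#'
#' Default method is a narrow zero-phase notch (biquad with its zero exactly
#' at the line frequency, -3 dB bandwidth `bw_hz`, applied forward-backward),
#' which nulls the line component while changing bands more than 2 Hz away by
#' well under 1 dB.  `method = "regression"` instead fits and subtracts a
#' single sine/cosine pair at the line frequency over the whole recording,
#' appropriate for a phase-stable interferer.
#'
#' @param recording an [eeg_recording()].
#' @param line_freq_hz line frequency in Hz (must be below Nyquist).
#' @param method `"notch"` or `"regression"`.
#' @param bw_hz -3 dB bandwidth of the notch in Hz.
#' @return The cleaned [eeg_recording()].
#' @export
remove_line_noise <- function(recording, line_freq_hz = 50,
                              method = c("notch", "regression"), bw_hz = 1) {
  stopifnot(inherits(recording, "eeg_recording"))
  method <- match.arg(method)
  fs <- recording$fs
  if (line_freq_hz >= fs / 2)
    stop_itfx("line frequency must be below Nyquist", class = "itfx_parameter_error")
  if (method == "notch") {
    co <- notch_coefficients(line_freq_hz, fs, bw_hz)
    pad <- as.integer(ceiling(2 * fs / bw_hz))
    recording$data <- filtfilt_padded(co$b, co$a, recording$data, pad)
  } else {
    t <- (seq_len(ncol(recording$data)) - 1) / fs
    X <- cbind(sin(2 * pi * line_freq_hz * t), cos(2 * pi * line_freq_hz * t))
    beta <- solve(crossprod(X), crossprod(X, t(recording$data)))
    recording$data <- recording$data - t(X %*% beta)
  }
  recording
}

#' Reject high-amplitude epochs
#'
#' Automated surrogate for visual artifact screening: any trial whose
#' peak-to-peak amplitude on any channel exceeds `reject_ptp_uv` is labeled
#' `"rejected"`.  Retained data are never altered, only labels.
#'
#' @param epochs an `eeg_epochs`.
#' @param reject_ptp_uv threshold in microvolts.
#' @return The `eeg_epochs` with updated labels and log.
#' @export
reject_epochs <- function(epochs, reject_ptp_uv = 150) {
  if (!is_scalar_num(reject_ptp_uv) || reject_ptp_uv <= 0)
    stop_itfx("reject_ptp_uv must be > 0", class = "itfx_parameter_error")
  candidates <- which(epochs$labels != "rejected")
  for (i in candidates) {
    x <- epochs$data[i, , , drop = FALSE]
    ptp <- apply(x, 2, function(ch) diff(range(ch)))
    if (max(ptp) > reject_ptp_uv) {
      epochs$labels[i] <- "rejected"
      epochs$log <- c(epochs$log,
                      sprintf("trial %d rejected: peak-to-peak %.1f uV > %.1f uV",
                              i, max(ptp), reject_ptp_uv))
    }
  }
  if (all(epochs$labels == "rejected"))
    stop_itfx("all trials exceeded the ", reject_ptp_uv,
              " uV peak-to-peak threshold; review the rejection threshold",
              class = "itfx_data_error")
  epochs
}

#' Run the continuous preprocessing chain
#'
#' Applies, in order: channel exclusion, high-pass filtering, line-noise
#' removal.  Epoch-level rejection ([reject_epochs()]) is applied after
#' epoching by the pipeline runner.
#'
#' @param recording an [eeg_recording()].
#' @param config a [preprocess_config()].
#' @return The conditioned [eeg_recording()].
#' @export
preprocess <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  drop <- recording$channel_labels %in% config$excluded_channels
  if (any(drop)) {
    recording$data <- recording$data[!drop, , drop = FALSE]
    recording$channel_labels <- recording$channel_labels[!drop]
  }
  recording <- highpass(recording, config$highpass_hz)
  remove_line_noise(recording, config$line_freq_hz)
}
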