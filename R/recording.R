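# The continuous-recording container and its constructors.

#' Construct a continuous EEG recording
#'
#' The basic container for continuous multichannel EEG: a channels x samples
#' matrix in microvolts, a sampling rate, and channel labels canonicalized to
#' the international 10-10 montage where possible.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate in samples per second (> 0).
#' @param channel_labels character vector, one unique label per channel.
#' @param meta free-form provenance list.
#' @return An object of class `eeg_recording` with elements `data`, `fs`,
#'   `channel_labels`, `meta`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(1000), nrow = 2), fs = 500,
#'                      channel_labels = c("Cz", "Pz"))
#' rec
eeg_recording <- function(data, fs, channel_labels, meta = list()) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_itfx("`data` must be a numeric channels x samples matrix",
              class = "itfx_format_error")
  if (nrow(data) == 0L)
    stop_itfx("recording has zero channels", class = "itfx_format_error")
  if (!is_scalar_num(fs) || fs <= 0)
    stop_itfx("`fs` must be a positive scalar", class = "itfx_parameter_error")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop_itfx("one channel label per data row is required",
              class = "itfx_format_error")
  if (anyDuplicated(channel_labels))
    stop_itfx("channel labels must be unique", class = "itfx_format_error")
  structure(list(data = data, fs = fs,
                 channel_labels = canonical_labels(channel_labels),
                 meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- ncol(x$data) / x$fs
  cat(sprintf("<eeg_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$data), ncol(x$data), dur, x$fs))
  cat("  channels:", paste(utils::head(x$channel_labels, 10), collapse = " "),
      if (length(x$channel_labels) > 10) "..." else "", "\n")
  invisible(x)
}

#' Duration of a recording in milliseconds
#' @param recording an [eeg_recording()].
#' @return duration in ms.
#' @export
recording_duration_ms <- function(recording) {
  ncol(recording$data) / recording$fs * 1000
}

#' Read a continuous EEG recording from disk
#'
#' Reads either a European Data Format (EDF) file or the package's plain-text
#' fixture container (see [write_fixture()]). With `format = "auto"` the
#' format is chosen by extension (`.edf` vs anything else).
#'
#' @param path path to the file.
#' @param format one of `"auto"`, `"edf"`, `"fixture"`.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "fixture")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_itfx("file not found: ", path, class = "itfx_io_error")
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "fixture"
  switch(format,
         edf = read_edf(path),
         fixture = read_fixture(path)$recording)
}
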