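# Minimal European Data Format (EDF) reader/writer.
#
# EDF stores an ASCII header (256 bytes + 256 per signal) followed by data
# records of 16-bit little-endian integers; physical values are recovered by
# linear scaling from the digital to the physical range.  Only continuous
# recordings with a common sampling rate across EEG signals are supported;
# "EDF Annotations" signals are skipped.

edf_field <- function(con, nchars) {
  trimws(rawToChar(readBin(con, "raw", n = nchars)))
}

#' Read an EDF file
#'
#' @param path path to a `.edf` file.
#' @return An [eeg_recording()]; header fields are kept in `meta`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_field(con, 8)
  patient <- edf_field(con, 80)
  recording_id <- edf_field(con, 80)
  start_date <- edf_field(con, 8)
  start_time <- edf_field(con, 8)
  header_bytes <- as.integer(edf_field(con, 8))
  reserved <- edf_field(con, 44)
  n_records <- as.integer(edf_field(con, 8))
  record_dur_s <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1)
    stop_itfx("EDF header declares zero signals", class = "itfx_format_error")

  rd <- function(nc) vapply(seq_len(ns), function(i) edf_field(con, nc), "")
  labels <- rd(16)
  transducer <- rd(80)
  dim_unit <- rd(8)
  phys_min <- as.numeric(rd(8))
  phys_max <- as.numeric(rd(8))
  dig_min <- as.numeric(rd(8))
  dig_max <- as.numeric(rd(8))
  prefilter <- rd(80)
  n_samp <- as.integer(rd(8))
  rd(32)  # per-signal reserved

  keep <- labels != "EDF Annotations"
  if (!any(keep))
    stop_itfx("EDF file contains no signal channels", class = "itfx_format_error")
  if (length(unique(n_samp[keep])) != 1L)
    stop_itfx("EDF signals with mixed sampling rates are not supported",
              class = "itfx_format_error")
  if (n_records < 0)
    stop_itfx("EDF with unknown record count is not supported",
              class = "itfx_format_error")

  spr <- n_samp[keep][1]
  fs <- spr / record_dur_s
  scale <- (phys_max - phys_min) / (dig_max - dig_min)

  data <- matrix(0, nrow = sum(keep), ncol = n_records * spr)
  for (r in seq_len(n_records)) {
    ki <- 0L
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = n_samp[s], size = 2,
                     signed = TRUE, endian = "little")
      if (keep[s]) {
        ki <- ki + 1L
        data[ki, (r - 1L) * spr + seq_len(spr)] <-
          phys_min[s] + (dig - dig_min[s]) * scale[s]
      }
    }
  }
  eeg_recording(data, fs = fs, channel_labels = labels[keep],
                meta = list(source = path, edf_version = version,
                            patient = patient, recording_id = recording_id,
                            start_date = start_date, start_time = start_time,
                            units = dim_unit[keep]))
}

edf_pad <- function(x, n) {
  x <- substr(as.character(x), 1, n)
  formatC(x, width = n, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Physical values are quantized to the EDF 16-bit digital range over a
#' symmetric physical range covering the data, so the round trip is exact to
#' roughly `max(abs(data))/32767` microvolts.
#'
#' @param recording an [eeg_recording()].
#' @param path output path.
#' @param record_dur_s data-record duration in seconds; must yield an integer
#'   number of samples per record.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, record_dur_s = 1) {
  data <- recording$data
  fs <- recording$fs
  spr <- fs * record_dur_s
  if (abs(spr - round(spr)) > 1e-9)
    stop_itfx("record duration must give an integer number of samples",
              class = "itfx_parameter_error")
  spr <- as.integer(round(spr))
  n_records <- floor(ncol(data) / spr)
  if (n_records < 1)
    stop_itfx("recording shorter than one data record",
              class = "itfx_parameter_error")
  ns <- nrow(data)
  pmax_ <- max(abs(data), 1e-6)
  phys_min <- -pmax_; phys_max <- pmax_
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeBin(charToRaw(paste0(edf_pad(x, n), collapse = "")), con)
  wr("0", 8); wr("X", 80); wr("itfx export", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + 256 * ns, 8); wr("", 44); wr(n_records, 8)
  wr(format(record_dur_s), 8); wr(ns, 4)
  for (f in list(list(recording$channel_labels, 16),
                 list(rep("", ns), 80), list(rep("uV", ns), 8),
                 list(rep(format(phys_min, digits = 7), ns), 8),
                 list(rep(format(phys_max, digits = 7), ns), 8),
                 list(rep(dig_min, ns), 8), list(rep(dig_max, ns), 8),
                 list(rep("", ns), 80), list(rep(spr, ns), 8),
                 list(rep("", ns), 32)))
    wr(f[[1]], f[[2]])

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_records)) {
    idx <- (r - 1L) * spr + seq_len(spr)
    for (s in seq_len(ns)) {
      dig <- round_half_away((data[s, idx] - phys_min) * scale + dig_min)
      dig <- as.integer(pmin(pmax(dig, dig_min), dig_max))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
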