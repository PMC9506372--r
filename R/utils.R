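# Shared helpers: sample/time mapping and small validators.

#' Round half away from zero
#'
#' Deterministic rounding used for all millisecond-to-sample conversions, so
#' that epoch and window boundaries are bit-reproducible across platforms
#' (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, halves away from zero.
#' @keywords internal
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# ms offset relative to an onset sample -> integer sample offset
ms_to_samples <- function(ms, fs) round_half_away(ms * fs / 1000)

stop_itfx <- function(..., class = "itfx_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Standard 10-10 montage labels used for canonicalization of channel names.
TEN_TEN_LABELS <- c(
  "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "Iz",
  "A1", "A2", "M1", "M2"
)

# Map arbitrary labels onto canonical 10-10 capitalization; unknown labels are
# kept verbatim and reported with a warning.
canonical_labels <- function(labels, warn = TRUE) {
  idx <- match(toupper(labels), toupper(TEN_TEN_LABELS))
  out <- ifelse(is.na(idx), labels, TEN_TEN_LABELS[idx])
  if (warn && anyNA(idx)) {
    warning("channel labels not in the 10-10 montage kept verbatim: ",
            paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out
}
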