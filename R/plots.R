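# Static QC figures: a time-frequency map per channel and a peak-matrix
# heatmap, base graphics only.

#' Plot an ERSP time-frequency map
#'
#' @param x an `eeg_ersp`.
#' @param channel channel label (default: first).
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.eeg_ersp <- function(x, channel = x$channels[1], ...) {
  ci <- match(channel, x$channels)
  if (is.na(ci))
    stop_itfx("channel not in the ERSP map: ", channel, class = "itfx_data_error")
  z <- t(x$ratio[ci, , ])
  graphics::image(x$times_ms, x$freqs_hz, z,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "time (ms)", ylab = "frequency (Hz)",
                  main = paste0("ERSP (baseline ratio) - ", channel), ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Plot a peak-frequency matrix
#'
#' Windows x electrodes heatmap of peak frequencies with the cell values
#' printed, colored by band (delta/theta/alpha/other).
#'
#' @param x a `peak_matrix`.
#' @param bands a [band_scheme()] used for coloring.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.peak_matrix <- function(x, bands = band_scheme(), ...) {
  nw <- nrow(x$peak_freq); ne <- ncol(x$peak_freq)
  band <- matrix(match(band_of(as.vector(x$peak_freq), bands),
                       c("delta", "theta", "alpha", "other")), nw, ne)
  cols <- c("#9ecae1", "#fdae6b", "#a1d99b", "#d9d9d9")
  graphics::image(seq_len(nw), seq_len(ne), band, col = cols, zlim = c(1, 4),
                  axes = FALSE, xlab = "time window", ylab = "",
                  main = "peak frequency per window x electrode (Hz)")
  graphics::axis(1, at = seq_len(nw),
                 labels = paste0(x$windows$start_ms, "-"), las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(ne), labels = x$electrodes, las = 1)
  for (w in seq_len(nw)) for (e in seq_len(ne))
    graphics::text(w, e, format(x$peak_freq[w, e]), cex = 0.55)
  invisible(x)
}
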