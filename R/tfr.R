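# Complex Morlet wavelet decomposition and event-related spectral
# perturbation (ERSP).
#
# Wavelets are Gaussian-windowed complex exponentials with a fixed number of
# cycles (default 7), i.e. sigma_t = n_cycles / (2*pi*f).  Each wavelet is
# normalized to unit peak frequency-domain gain, so a pure sinusoid of
# amplitude a yields squared-magnitude a^2/4 at its own frequency, identically
# across the frequency grid; the normalization cancels in the ERSP ratio in
# any case.  Convolution is done by FFT with reflection padding of (up to)
# half the longest wavelet at each end to mitigate edge effects.

# Complex Morlet wavelet sampled at fs; support +-4 sigma_t.
morlet_wavelet <- function(freq, fs, n_cycles = 7) {
  sigma_t <- n_cycles / (2 * pi * freq)
  half <- as.integer(ceiling(4 * sigma_t * fs))
  t <- seq(-half, half) / fs
  env <- exp(-t^2 / (2 * sigma_t^2))
  w <- env * exp(2i * pi * freq * t)
  list(w = w / sum(env), half = half)  # unit gain at `freq` for a pure tone
}

#' Morlet wavelet power decomposition
#'
#' Per-trial, per-channel squared magnitude of the convolution with complex
#' Morlet wavelets (default 7 cycles) on a 1-15 Hz grid in 0.5 Hz steps.
#' Epochs are reflection-padded before the FFT convolution; time points
#' closer to an epoch edge than half a wavelet are flagged in `edge`.
#'
#' @param epochs an `eeg_epochs`.
#' @param freqs_hz strictly increasing frequency grid in Hz (< Nyquist).
#' @param n_cycles wavelet width in cycles.
#' @param channels channel labels to decompose (default: all).
#' @param trials integer trial indices (default: all non-rejected trials).
#' @return An `eeg_tfr`: `power` (trials x channels x frequencies x times,
#'   microvolts squared), `freqs_hz`, `times_ms`, `channels`, `trials`,
#'   `n_cycles`, `edge` (frequencies x times logical).
#' @export
morlet_power <- function(epochs, freqs_hz = seq(1, 15, by = 0.5), n_cycles = 7,
                         channels = NULL, trials = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  fs <- epochs$fs
  if (any(freqs_hz >= fs / 2))
    stop_itfx("all frequencies must be below the Nyquist frequency ", fs / 2,
              " Hz", class = "itfx_parameter_error")
  if (any(freqs_hz <= 0) || is.unsorted(freqs_hz, strictly = TRUE))
    stop_itfx("freqs_hz must be positive and strictly increasing",
              class = "itfx_parameter_error")
  channels <- channels %||% epochs$channel_labels
  ch_idx <- match(channels, epochs$channel_labels)
  if (anyNA(ch_idx))
    stop_itfx("channels not present: ",
              paste(channels[is.na(ch_idx)], collapse = ", "),
              "; available: ", paste(epochs$channel_labels, collapse = ", "),
              class = "itfx_data_error")
  trials <- trials %||% which(epochs$labels != "rejected")
  if (length(trials) < 1)
    stop_itfx("no trials to decompose", class = "itfx_data_error")

  n <- length(epochs$times_ms)
  wavelets <- lapply(freqs_hz, morlet_wavelet, fs = fs, n_cycles = n_cycles)
  halves <- vapply(wavelets, `[[`, integer(1), "half")
  pad <- min(n - 1L, max(halves))
  npad <- n + 2L * pad
  # mixed-radix length: any circular wrap-around falls inside the reflection
  # pads plus the edge-flagged margin of the longest (lowest-frequency) wavelet
  nfft <- stats::nextn(npad, c(2, 3, 5))

  # wavelet spectra, wavelet centered at sample 1 with circular wrap
  wf <- lapply(wavelets, function(wl) {
    v <- complex(length.out = nfft)
    h <- wl$half
    v[seq_len(h + 1L)] <- wl$w[(h + 1L):(2L * h + 1L)]
    v[(nfft - h + 1L):nfft] <- wl$w[seq_len(h)]
    stats::fft(v)
  })

  nt <- length(trials); nc <- length(ch_idx); nf <- length(freqs_hz)
  power <- array(NA_real_, dim = c(nt, nc, nf, n))
  head_idx <- seq(pad + 1L, 2L)
  tail_idx <- seq(n - 1L, n - pad)
  for (ci in seq_len(nc)) {
    X <- matrix(0, nrow = nfft, ncol = nt)
    for (ti in seq_len(nt)) {
      x <- epochs$data[trials[ti], ch_idx[ci], ]
      X[seq_len(npad), ti] <- c(x[head_idx], x, x[tail_idx])
    }
    FX <- stats::mvfft(X)
    for (fi in seq_len(nf)) {
      Y <- stats::mvfft(FX * wf[[fi]], inverse = TRUE)[pad + seq_len(n), ,
                                                       drop = FALSE] / nfft
      power[, ci, fi, ] <- t(Mod(Y)^2)
    }
  }

  edge <- matrix(FALSE, nrow = nf, ncol = n)
  for (fi in seq_len(nf))
    edge[fi, ] <- seq_len(n) <= halves[fi] | seq_len(n) > n - halves[fi]

  structure(list(power = power, freqs_hz = freqs_hz, times_ms = epochs$times_ms,
                 channels = channels, trials = trials, n_cycles = n_cycles,
                 fs = fs, baseline_ms = epochs$baseline_ms, edge = edge),
            class = "eeg_tfr")
}

#' @export
print.eeg_tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<eeg_tfr> %d trials x %d channels x %d freqs (%.1f-%.1f Hz) x %d times, %d cycles\n",
              d[1], d[2], d[3], min(x$freqs_hz), max(x$freqs_hz), d[4], x$n_cycles))
  invisible(x)
}

#' Event-related spectral perturbation (baseline-ratio power)
#'
#' Averages single-trial wavelet power over trials and expresses it as a
#' ratio against the mean pre-stimulus baseline power, per channel and
#' frequency, on the analysis grid (default 2-15 Hz).
#'
#' Two baseline orders are provided. `trial_norm = "average"` (default)
#' averages `|X|^2` over trials first and divides by the baseline mean of
#' that average -- the ratio applied to the trial-averaged power.
#' `trial_norm = "single"` divides each trial by its own baseline mean and
#' then averages the ratios; with short baselines and few cycles per baseline
#' window the single-trial baseline mean is low-precision at the lowest
#' frequencies, which inflates that variant's expected ratio there (see the
#' methods vignette).
#'
#' @param tfr an `eeg_tfr` from [morlet_power()].
#' @param baseline_ms half-open baseline interval in ms (default -800..0).
#' @param analysis_freqs two-element range; frequencies of `tfr` within it are
#'   reported (default 2-15 Hz).
#' @param trial_norm `"average"` or `"single"` (see Details).
#' @return An `eeg_ersp`: `ratio` (channels x frequencies x times,
#'   dimensionless), `freqs_hz`, `times_ms`, `channels`, `n_trials`, `edge`.
#' @export
ersp <- function(tfr, baseline_ms = NULL, analysis_freqs = c(2, 15),
                 trial_norm = c("average", "single")) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  trial_norm <- match.arg(trial_norm)
  baseline_ms <- baseline_ms %||% tfr$baseline_ms
  bsel <- tfr$times_ms >= baseline_ms[1] & tfr$times_ms < baseline_ms[2]
  if (!any(bsel))
    stop_itfx("baseline interval contains no samples", class = "itfx_parameter_error")
  fsel <- tfr$freqs_hz >= analysis_freqs[1] & tfr$freqs_hz <= analysis_freqs[2]
  if (!any(fsel))
    stop_itfx("no frequencies inside the analysis range", class = "itfx_parameter_error")

  p <- tfr$power[, , fsel, , drop = FALSE]
  d <- dim(p)  # trials, channels, freqs, times
  freqs <- tfr$freqs_hz[fsel]

  if (trial_norm == "single") {
    base <- rowMeans(p[, , , bsel, drop = FALSE], dims = 3)
    bad <- which(base <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop_itfx(sprintf("zero baseline power in trial %d, channel %s, %.1f Hz",
                        tfr$trials[bad[1, 1]], tfr$channels[bad[1, 2]],
                        freqs[bad[1, 3]]),
                class = "itfx_data_error")
    ratio <- colMeans(p / as.vector(base), dims = 1)        # recycle over times
  } else {
    avg <- colMeans(p, dims = 1)                            # channels x freqs x times
    base <- rowMeans(avg[, , bsel, drop = FALSE], dims = 2)
    bad <- which(base <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop_itfx(sprintf("zero baseline power in channel %s, %.1f Hz",
                        tfr$channels[bad[1, 1]], freqs[bad[1, 2]]),
                class = "itfx_data_error")
    ratio <- sweep(avg, c(1, 2), base, "/")
  }
  dimnames(ratio) <- list(tfr$channels, format(freqs), NULL)
  structure(list(ratio = ratio, freqs_hz = freqs, times_ms = tfr$times_ms,
                 channels = tfr$channels, n_trials = d[1],
                 baseline_ms = baseline_ms, trial_norm = trial_norm,
                 edge = tfr$edge[fsel, , drop = FALSE]),
            class = "eeg_ersp")
}

#' @export
print.eeg_ersp <- function(x, ...) {
  cat(sprintf("<eeg_ersp> %d channels x %d freqs (%.1f-%.1f Hz) x %d times; %d trials, %s-trial baseline ratio\n",
              length(x$channels), length(x$freqs_hz), min(x$freqs_hz),
              max(x$freqs_hz), length(x$times_ms), x$n_trials, x$trial_norm))
  invisible(x)
}

# Stack two ERSP maps (same trials/frequencies/times) along the channel axis.
combine_ersp <- function(e1, e2) {
  stopifnot(identical(e1$freqs_hz, e2$freqs_hz),
            identical(e1$times_ms, e2$times_ms),
            e1$n_trials == e2$n_trials,
            identical(e1$trial_norm, e2$trial_norm))
  ratio <- array(NA_real_, dim = c(length(e1$channels) + length(e2$channels),
                                   length(e1$freqs_hz), length(e1$times_ms)))
  ratio[seq_along(e1$channels), , ] <- e1$ratio
  ratio[length(e1$channels) + seq_along(e2$channels), , ] <- e2$ratio
  e1$channels <- c(e1$channels, e2$channels)
  dimnames(ratio) <- list(e1$channels, format(e1$freqs_hz), NULL)
  e1$ratio <- ratio
  e1
}

#' Export an ERSP map as long-format TSV
#'
#' Columns: channel, freq_hz, time_ms, ratio.
#'
#' @param ersp an `eeg_ersp`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ersp_tsv <- function(ersp, path) {
  df <- expand.grid(channel = ersp$channels, freq_hz = ersp$freqs_hz,
                    time_ms = ersp$times_ms, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$ratio <- as.vector(ersp$ratio)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
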