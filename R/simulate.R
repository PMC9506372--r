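# Synthetic EEG sessions with the statistical structure the method assumes:
# 1/f background noise, a waxing-and-waning posterior alpha rhythm, and
# event-locked theta bursts of known frequency on centroparietal channels for
# to-be-successfully-encoded trials, plus matched event and behavior tables.

SIM_CHANNELS <- c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8", "T7", "T8",
                  "Cz", "C3", "C4", "CP5", "CP6", "Pz", "P3", "P4",
                  "PO7", "PO8", "Oz")
CENTROPARIETAL <- c("Cz", "C3", "C4", "Pz", "P3", "P4")
POSTERIOR <- c("PO7", "PO8", "Oz")

# Posterior-to-anterior alpha amplitude gradient (fraction of alpha_amp_uv):
# occipital/parieto-occipital sites carry full alpha, parietal ~60%,
# central ~30%, frontal/temporal ~10% -- the classic eyes-open topography.
alpha_gradient <- function(label) {
  if (label %in% POSTERIOR) 1
  else if (label %in% c("Pz", "P3", "P4", "CP5", "CP6")) 0.6
  else if (label %in% c("Cz", "C3", "C4", "T7", "T8")) 0.3
  else 0.1
}

#' Simulation parameters
#'
#' Defaults describe a realistic single session of the paired-associates
#' design: 42 face-scene pairs presented for 2000 ms with a 1250-1750 ms
#' inter-stimulus interval at 500 Hz over a 20-channel 10-10 montage, a hit
#' rate of 59.5% and a correct-rejection rate of 68.5% (typical young-adult
#' performance on this task), pink (1/f) background noise of about 10 uV RMS,
#' a 10 Hz posterior alpha rhythm, and sustained Hann-windowed theta bursts
#' at `theta_freq_hz` starting around 300 ms post-onset (jittered) and
#' lasting 1500 ms, scaled so that their peak wavelet power is `burst_snr`
#' times the background power at that frequency.
#'
#' The default burst covers the whole scanned 250-1250 ms interval and
#' extends beyond it: a burst much shorter than ~1 s does not carry a
#' frequency resolvable on the 0.5 Hz analysis grid (its spectral width,
#' combined with the wavelet bandwidth growing as f/7 and the 1/f-shaped
#' baseline in the ERSP ratio, pushes the noise-free peak half a step above
#' the planted frequency), so the truth record would be wrong by
#' construction.  See the methods vignette.
#'
#' @param fs sampling rate, samples/s.
#' @param n_pairs number of encoding pairs (recognition shows `2 * n_pairs`).
#' @param theta_freq_hz planted theta frequency, on the 0.5 Hz grid in
#'   `[4, 7.5]`.
#' @param burst_onset_ms nominal burst onset after the stimulus, ms.
#' @param jitter_sd_ms SD of the Gaussian onset jitter (truncated so that
#'   short bursts stay inside the scanned 250-1250 ms interval and
#'   window-covering bursts start between 250 and 350 ms).
#' @param burst_duration_ms burst length, ms.
#' @param burst_snr burst wavelet power over background power at
#'   `theta_freq_hz`; `0` plants no burst.
#' @param alpha_freq_hz alpha center frequency.
#' @param alpha_amp_uv alpha RMS amplitude at the occipital/parieto-occipital
#'   sites (PO7/PO8/Oz); other channels follow a posterior-to-anterior
#'   gradient (parietal 60%, central 30%, frontal/temporal 10%).
#' @param alpha_bw_hz alpha bandwidth (SD of its spectral envelope).
#' @param noise_exponent spectral slope of the 1/f background.
#' @param noise_rms_uv background RMS amplitude per channel.
#' @param hit_rate fraction of intact pairs judged "old"; exactly
#'   `round(hit_rate * n_pairs)` encoding trials become successful.
#' @param cr_rate fraction of recombined pairs judged "recombined".
#' @param stim_duration_ms,isi_range_ms encoding presentation timing.
#' @param n_artifact_trials encoding trials contaminated with a large
#'   transient (for rejection tests).
#' @param artifact_amp_uv amplitude of the planted artifact.
#' @param seed RNG seed; fixes the session byte-for-byte.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(fs = 500, n_pairs = 42, theta_freq_hz = 5,
                       burst_onset_ms = 300, jitter_sd_ms = 50,
                       burst_duration_ms = 1500, burst_snr = 3,
                       alpha_freq_hz = 10, alpha_amp_uv = 6, alpha_bw_hz = 1,
                       noise_exponent = 1, noise_rms_uv = 10,
                       hit_rate = 0.595, cr_rate = 0.685,
                       stim_duration_ms = 2000, isi_range_ms = c(1250, 1750),
                       n_artifact_trials = 0, artifact_amp_uv = 500,
                       seed = 1) {
  p <- as.list(environment())
  if (p$theta_freq_hz < 4 || p$theta_freq_hz > 7.5 ||
      abs(p$theta_freq_hz / 0.5 - round(p$theta_freq_hz / 0.5)) > 1e-9)
    stop_itfx("theta_freq_hz must lie on the 0.5 Hz grid within [4, 7.5]",
              class = "itfx_parameter_error")
  if (p$hit_rate <= 0 || p$hit_rate > 1 || round(p$hit_rate * p$n_pairs) < 1)
    stop_itfx("hit_rate must give at least one successful trial",
              class = "itfx_parameter_error")
  if (p$burst_snr < 0)
    stop_itfx("burst_snr must be >= 0", class = "itfx_parameter_error")
  structure(p, class = "sim_params")
}

# Gaussian noise with a prescribed spectral amplitude envelope, synthesized
# in the frequency domain at an FFT-friendly length and truncated to n
# (truncation of a stationary process leaves its law unchanged).
spectral_noise <- function(n, fs, amp_fn, rms) {
  n2 <- stats::nextn(n, c(2, 3, 5))
  nf <- n2 %/% 2
  f <- seq_len(nf) * fs / n2
  spec <- amp_fn(f) * complex(real = stats::rnorm(nf),
                              imaginary = stats::rnorm(nf))
  full <- complex(length.out = n2)
  full[2:(nf + 1)] <- spec
  full[n2:(n2 - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  x * rms / stats::sd(x)
}

# 1/f^exponent background; slope relative to a 1 Hz reference.
one_over_f_noise <- function(n, fs, exponent, rms) {
  spectral_noise(n, fs, function(f) f^(-exponent / 2), rms)
}

# Waxing-and-waning alpha: a narrowband Gaussian carrier around f0 times a
# slow Rayleigh envelope (correlation time ~1 s), emulating the
# second-scale blocking/burst episodes of real eyes-open alpha.  A
# stationary narrowband process alone fluctuates too little between the
# baseline and analysis seconds of an epoch to produce the alpha-dominant
# resting peak matrices seen in practice.
alpha_rhythm <- function(n, fs, f0, bw, rms) {
  carrier <- spectral_noise(n, fs, function(f) exp(-(f - f0)^2 / (2 * bw^2)), 1)
  lowpass <- function(f) exp(-f^2 / (2 * 0.15^2))
  m <- sqrt(spectral_noise(n, fs, lowpass, 1)^2 +
              spectral_noise(n, fs, lowpass, 1)^2)
  x <- carrier * m
  x * rms / stats::sd(x)
}

# Linear convolution with a (complex) wavelet at an FFT-friendly length,
# returned aligned to x.
fft_filter <- function(x, w) {
  nx <- length(x); nw <- length(w); h <- (nw - 1L) %/% 2L
  nfft <- stats::nextn(nx + nw - 1L, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - nx)))
  W <- stats::fft(c(w, complex(length.out = nfft - nw)))
  y <- stats::fft(X * W, inverse = TRUE) / nfft
  y[h + seq_len(nx)]
}

# Mean wavelet power of signal x at one frequency (interior samples only).
mean_wavelet_power <- function(x, fs, freq, n_cycles = 7) {
  wl <- morlet_wavelet(freq, fs, n_cycles)
  y <- fft_filter(x, wl$w)
  core <- y[(wl$half + 1):(length(x) - wl$half)]
  mean(Mod(core)^2)
}

# Peak wavelet power of a unit-amplitude Hann burst at its own frequency.
unit_burst_peak_power <- function(fs, freq, duration_ms, n_cycles = 7) {
  ns <- as.integer(round_half_away(duration_ms * fs / 1000))
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, ns - 1) / (ns - 1))
  burst <- hann * sin(2 * pi * freq * seq(0, ns - 1) / fs)
  pad <- as.integer(2 * fs)
  x <- c(numeric(pad), burst, numeric(pad))
  wl <- morlet_wavelet(freq, fs, n_cycles)
  max(Mod(fft_filter(x, wl$w))^2)
}

#' Simulate an associative-memory EEG session
#'
#' Generates continuous 20-channel EEG for the encoding block (1/f noise +
#' posterior-dominant alpha + theta bursts on centroparietal channels,
#' time-locked with jitter to the onsets of to-be-successful trials), the
#' event table for both blocks (recognition shows `n_pairs` intact and
#' `n_pairs` recombined pairs; the recording itself covers the encoding
#' block, which is the analyzed signal), a behavior table realizing the
#' requested hit and correct-rejection rates, and a truth record with the
#' planted frequency and the successful-trial set.
#'
#' The burst amplitude is calibrated per session against the empirically
#' measured background wavelet power at `theta_freq_hz`, so the planted
#' burst's peak event-related power ratio is approximately
#' `1 + burst_snr`.
#'
#' @param params a [sim_params()].
#' @return A list of class `itf_simulation`: `recording`, `events`,
#'   `behavior`, `truth`.
#' @export
#' @examples
#' sim <- simulate_session(sim_params(n_pairs = 4, seed = 42))
#' sim$truth$theta_freq_hz
simulate_session <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  fs <- p$fs

  # --- encoding timeline ---------------------------------------------------
  lead_in_ms <- 2000
  isi <- stats::runif(p$n_pairs - 1, p$isi_range_ms[1], p$isi_range_ms[2])
  enc_onsets <- lead_in_ms + c(0, cumsum(p$stim_duration_ms + isi))
  tail_ms <- 3000
  total_ms <- enc_onsets[p$n_pairs] + p$stim_duration_ms + tail_ms
  n <- as.integer(round_half_away(total_ms * fs / 1000))

  # --- background + alpha --------------------------------------------------
  data <- matrix(0, nrow = length(SIM_CHANNELS), ncol = n,
                 dimnames = list(SIM_CHANNELS, NULL))
  for (ci in seq_along(SIM_CHANNELS)) {
    a_amp <- p$alpha_amp_uv * alpha_gradient(SIM_CHANNELS[ci])
    data[ci, ] <- one_over_f_noise(n, fs, p$noise_exponent, p$noise_rms_uv) +
      alpha_rhythm(n, fs, p$alpha_freq_hz, p$alpha_bw_hz, a_amp)
  }

  # --- behavior ------------------------------------------------------------
  n_hits <- as.integer(round_half_away(p$hit_rate * p$n_pairs))
  successful <- sort(sample.int(p$n_pairs, n_hits))
  pair_ids <- sprintf("P%02d", seq_len(p$n_pairs))

  # --- theta bursts on to-be-successful trials -----------------------------
  burst_onsets_ms <- rep(NA_real_, p$n_pairs)
  burst_amp <- 0
  if (p$burst_snr > 0 && length(successful) > 0) {
    cp_idx <- match(CENTROPARIETAL, SIM_CHANNELS)
    p0 <- mean(vapply(cp_idx[c(1, 4)], function(ci)
      mean_wavelet_power(data[ci, seq_len(min(n, 30 * fs))], fs, p$theta_freq_hz),
      numeric(1)))
    r1 <- unit_burst_peak_power(fs, p$theta_freq_hz, p$burst_duration_ms)
    burst_amp <- sqrt(p$burst_snr * p0 / r1)

    ns_b <- as.integer(round_half_away(p$burst_duration_ms * fs / 1000))
    hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, ns_b - 1) / (ns_b - 1))
    # Onset jitter clamp: short bursts stay inside the scanned 250-1250 ms
    # interval; window-covering bursts (>= 900 ms) start at 250-350 ms and
    # run past the window's end (while fitting the epoch).
    lo <- 250
    hi <- min(max(1250 - p$burst_duration_ms, lo + 100),
              2400 - p$burst_duration_ms)
    hi <- max(hi, lo)
    for (tr in successful) {
      onset_b <- min(max(p$burst_onset_ms + stats::rnorm(1, 0, p$jitter_sd_ms), lo), hi)
      burst_onsets_ms[tr] <- onset_b
      i0 <- as.integer(ms_to_samples(enc_onsets[tr] + onset_b, fs)) + 1L
      phase <- stats::runif(1, 0, 2 * pi)
      burst <- burst_amp * hann * sin(2 * pi * p$theta_freq_hz * seq(0, ns_b - 1) / fs + phase)
      idx <- i0:(i0 + ns_b - 1L)
      data[cp_idx, idx] <- sweep(data[cp_idx, idx, drop = FALSE], 2, burst, "+")
    }
  }

  # --- planted artifacts ---------------------------------------------------
  artifact_trials <- integer()
  if (p$n_artifact_trials > 0) {
    artifact_trials <- sort(sample.int(p$n_pairs, p$n_artifact_trials))
    for (tr in artifact_trials) {
      i0 <- as.integer(ms_to_samples(enc_onsets[tr] + 500, fs)) + 1L
      data[1, i0:(i0 + as.integer(0.1 * fs))] <-
        data[1, i0:(i0 + as.integer(0.1 * fs))] + p$artifact_amp_uv
    }
  }

  # --- event table (recognition follows the encoding block) ---------------
  n_rec <- 2L * p$n_pairs
  rec_gap_ms <- 5000
  rec_isi <- stats::runif(n_rec, 1500, 2000)
  rec_onsets <- total_ms + rec_gap_ms + cumsum(rec_isi + 3000) - (rec_isi[1] + 3000)
  shift <- c(seq(2, p$n_pairs), 1)  # cyclic re-pairing for recombined pairs
  rec_kind <- sample(rep(c("old", "recombined"), each = p$n_pairs))
  old_order <- sample.int(p$n_pairs)
  reco_order <- sample.int(p$n_pairs)
  oi <- 0L; ri <- 0L
  rec_pair <- character(n_rec); rec_truth <- character(n_rec)
  for (k in seq_len(n_rec)) {
    if (rec_kind[k] == "old") {
      oi <- oi + 1L
      rec_pair[k] <- pair_ids[old_order[oi]]
      rec_truth[k] <- "old"
    } else {
      ri <- ri + 1L
      j <- reco_order[ri]
      rec_pair[k] <- paste0(pair_ids[j], "|", pair_ids[shift[j]])
      rec_truth[k] <- "recombined"
    }
  }
  events <- rbind(
    data.frame(onset_ms = enc_onsets, block = "encoding",
               trial_id = sprintf("E%02d", seq_len(p$n_pairs)),
               pair_id = pair_ids, stringsAsFactors = FALSE),
    data.frame(onset_ms = rec_onsets, block = "recognition",
               trial_id = sprintf("R%02d", seq_len(n_rec)),
               pair_id = rec_pair, stringsAsFactors = FALSE))

  # --- behavior table ------------------------------------------------------
  old_resp <- ifelse(match(rec_pair[rec_truth == "old"], pair_ids) %in% successful,
                     "old", "recombined")
  n_cr <- as.integer(round_half_away(p$cr_rate * p$n_pairs))
  cr_correct <- seq_len(p$n_pairs) %in% sample.int(p$n_pairs, n_cr)
  reco_resp <- ifelse(cr_correct, "recombined", "old")
  behavior <- data.frame(trial_id = events$trial_id[events$block == "recognition"],
                         truth = rec_truth,
                         response = NA_character_, stringsAsFactors = FALSE)
  behavior$response[rec_truth == "old"] <- old_resp
  behavior$response[rec_truth == "recombined"] <- reco_resp

  recording <- eeg_recording(data, fs = fs, channel_labels = SIM_CHANNELS,
                             meta = list(simulated = TRUE, seed = p$seed,
                                         recognition_eeg = FALSE))
  truth <- list(theta_freq_hz = p$theta_freq_hz,
                successful_pairs = pair_ids[successful],
                burst_onsets_ms = burst_onsets_ms,
                burst_amp_uv = burst_amp,
                artifact_trials = artifact_trials,
                params = p)
  structure(list(recording = recording, events = events,
                 behavior = behavior, truth = truth),
            class = "itf_simulation")
}

#' Simulate a resting-state recording
#'
#' Stationary eyes-open rest: 1/f background plus posterior-dominant alpha,
#' with no event-locked theta.
#'
#' @param params a [sim_params()] (alpha/noise fields are used).
#' @param duration_s recording length in seconds (>= 3.5).
#' @return An [eeg_recording()].
#' @export
simulate_resting <- function(params = sim_params(), duration_s = 180) {
  stopifnot(inherits(params, "sim_params"))
  if (duration_s < 3.5)
    stop_itfx("resting recording must be at least 3.5 s",
              class = "itfx_parameter_error")
  p <- params
  set.seed(p$seed + 10000L)
  n <- as.integer(round_half_away(duration_s * p$fs))
  data <- matrix(0, nrow = length(SIM_CHANNELS), ncol = n,
                 dimnames = list(SIM_CHANNELS, NULL))
  for (ci in seq_along(SIM_CHANNELS)) {
    a_amp <- p$alpha_amp_uv * alpha_gradient(SIM_CHANNELS[ci])
    data[ci, ] <- one_over_f_noise(n, p$fs, p$noise_exponent, p$noise_rms_uv) +
      alpha_rhythm(n, p$fs, p$alpha_freq_hz, p$alpha_bw_hz, a_amp)
  }
  eeg_recording(data, fs = p$fs, channel_labels = SIM_CHANNELS,
                meta = list(simulated = TRUE, resting = TRUE, seed = p$seed))
}
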