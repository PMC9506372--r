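# Builders for small synthetic inputs and independent oracles.

SYNTH_LABELS <- c("Cz", "Pz", "C3", "C4", "P3", "P4", "PO7", "PO8")

# Recording holding given per-channel signal functions of time (seconds).
make_recording <- function(fun_list, dur_s, fs = 500,
                           labels = SYNTH_LABELS[seq_along(fun_list)]) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  data <- do.call(rbind, lapply(fun_list, function(f) f(t)))
  eeg_recording(data, fs = fs, channel_labels = labels)
}

# Epochs cut from a single-channel (or multi-channel) signal with onsets
# spaced well apart; signal functions receive time in seconds from
# recording start.
make_epochs <- function(fun_list, n_trials = 4, fs = 500,
                        labels = SYNTH_LABELS[seq_along(fun_list)],
                        t0_ms = -1000, t1_ms = 2500) {
  spacing_ms <- (t1_ms - t0_ms) + 500
  onsets <- seq(max(1500, -t0_ms + 500), by = spacing_ms, length.out = n_trials)
  dur_s <- (max(onsets) + t1_ms + 1000) / 1000
  rec <- make_recording(fun_list, dur_s, fs, labels)
  epoch(rec, data.frame(onset_ms = onsets), t0_ms = t0_ms, t1_ms = t1_ms)
}

# Epochs of white Gaussian noise.
make_noise_epochs <- function(n_trials = 20, n_channels = 1, fs = 500, sd = 10,
                              seed = 1) {
  set.seed(seed)
  funs <- replicate(n_channels, function(t) rnorm(length(t), sd = sd),
                    simplify = FALSE)
  make_epochs(funs, n_trials = n_trials, fs = fs)
}

# Hand-built ERSP map (fixture constructor mirroring the eeg_ersp layout).
make_ersp_map <- function(ratio, freqs_hz, times_ms, channels) {
  structure(list(ratio = ratio, freqs_hz = freqs_hz, times_ms = times_ms,
                 channels = channels, n_trials = 1L, baseline_ms = c(-800, 0),
                 trial_norm = "average",
                 edge = matrix(FALSE, length(freqs_hz), length(times_ms))),
            class = "eeg_ersp")
}

# ERSP map with ratio 1 everywhere plus a ridge of given height at one
# frequency on chosen channels/time range.
ridge_ersp <- function(ridge_hz, height = 3, channels = c("Cz", "C3", "C4", "Pz", "P3", "P4"),
                       ridge_channels = channels, freqs_hz = seq(2, 15, 0.5),
                       times_ms = seq(-1000, 2498, by = 2),
                       ridge_window_ms = c(250, 1250)) {
  ratio <- array(1, dim = c(length(channels), length(freqs_hz), length(times_ms)))
  fi <- match(ridge_hz, freqs_hz)
  stopifnot(!is.na(fi))
  tsel <- times_ms >= ridge_window_ms[1] & times_ms < ridge_window_ms[2]
  ratio[match(ridge_channels, channels), fi, tsel] <- height
  make_ersp_map(ratio, freqs_hz, times_ms, channels)
}

# Peak-matrix fixture from a vector of cell frequencies (for band/mode tests).
make_peak_matrix <- function(freqs, ersp_vals = rep(1, length(freqs)),
                             n_electrodes = 1) {
  nw <- length(freqs) / n_electrodes
  structure(list(peak_freq = matrix(freqs, nw, n_electrodes),
                 peak_ersp = matrix(ersp_vals, nw, n_electrodes),
                 windows = data.frame(start_ms = seq_len(nw), end_ms = seq_len(nw) + 1),
                 electrodes = paste0("E", seq_len(n_electrodes)),
                 freqs_hz = sort(unique(freqs))),
            class = "peak_matrix")
}

# Independent brute-force oracle for the peak matrix: plain nested loops,
# no shared code with peak_matrix() internals.
brute_force_peak_matrix <- function(ersp, windows, electrodes) {
  nw <- nrow(windows)
  pf <- matrix(NA_real_, nw, length(electrodes))
  pe <- matrix(NA_real_, nw, length(electrodes))
  for (w in seq_len(nw)) {
    for (e in seq_along(electrodes)) {
      ei <- which(ersp$channels == electrodes[e])
      best_f <- NA_real_; best_v <- -Inf
      for (fi in seq_along(ersp$freqs_hz)) {
        acc <- 0; cnt <- 0
        for (ti in seq_along(ersp$times_ms)) {
          tm <- ersp$times_ms[ti]
          if (tm >= windows$start_ms[w] && tm < windows$end_ms[w]) {
            acc <- acc + ersp$ratio[ei, fi, ti]
            cnt <- cnt + 1
          }
        }
        v <- acc / cnt
        if (v > best_v) { best_v <- v; best_f <- ersp$freqs_hz[fi] }
      }
      pf[w, e] <- best_f
      pe[w, e] <- best_v
    }
  }
  list(peak_freq = pf, peak_ersp = pe)
}

# Random small ERSP array for oracle-equivalence checks.
random_ersp <- function(seed, n_channels = 3, n_freqs = 8, n_times = 40) {
  set.seed(seed)
  channels <- paste0("CH", seq_len(n_channels))
  freqs <- seq(2, by = 0.5, length.out = n_freqs)
  times <- seq(0, by = 25, length.out = n_times)
  ratio <- array(stats::rexp(n_channels * n_freqs * n_times),
                 dim = c(n_channels, n_freqs, n_times))
  make_ersp_map(ratio, freqs, times, channels)
}

# Small-but-complete toy task: n pairs, intact + recombined recognition.
toy_task <- function(n_pairs = 4, responses_old = rep("old", n_pairs)) {
  pair <- sprintf("P%d", seq_len(n_pairs))
  events <- rbind(
    data.frame(onset_ms = seq(0, by = 3500, length.out = n_pairs),
               block = "encoding", trial_id = sprintf("E%d", seq_len(n_pairs)),
               pair_id = pair),
    data.frame(onset_ms = seq(100000, by = 4000, length.out = 2 * n_pairs),
               block = "recognition",
               trial_id = sprintf("R%d", seq_len(2 * n_pairs)),
               pair_id = c(pair, paste0(pair, "|", rev(pair)))))
  behavior <- data.frame(trial_id = sprintf("R%d", seq_len(2 * n_pairs)),
                         truth = rep(c("old", "recombined"), each = n_pairs),
                         response = c(responses_old, rep("recombined", n_pairs)))
  list(events = events, behavior = behavior)
}
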