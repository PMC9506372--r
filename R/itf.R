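# The core contribution: the overlapping time-window x electrode
# peak-frequency matrix, band shares, modal theta extraction with a
# reliability score and five-class scale, the parieto-occipital fallback,
# and the task-vs-rest theta-share contrast.

#' Overlapping analysis windows
#'
#' Enumerates half-open windows `[s, s+width)` for `s = start, start+step,
#' ...` while `s + width <= end`.  The defaults reproduce the 19 windows
#' from 250-350 ms through 1150-1250 ms used for ITF extraction.
#'
#' @param start_ms,end_ms scanned interval in ms post-onset.
#' @param width_ms window width in ms.
#' @param step_ms step between window starts in ms.
#' @return A `data.frame` with columns `start_ms`, `end_ms`.
#' @export
#' @examples
#' nrow(make_time_windows())  # 19
make_time_windows <- function(start_ms = 250, end_ms = 1250, width_ms = 100,
                              step_ms = 50) {
  if (width_ms <= 0 || step_ms <= 0 || start_ms < 0)
    stop_itfx("window parameters must be positive", class = "itfx_parameter_error")
  if (width_ms > end_ms - start_ms)
    stop_itfx("window width exceeds the scanned interval",
              class = "itfx_parameter_error")
  starts <- seq(start_ms, end_ms - width_ms, by = step_ms)
  data.frame(start_ms = starts, end_ms = starts + width_ms)
}

#' Frequency-band scheme
#'
#' Half-open bands on the 0.5 Hz analysis grid: delta `[2, 4)`, theta
#' `[4, 8)`, alpha `[8, 12]`; anything above 12 Hz counts as `other`.
#' Theta therefore holds exactly eight candidate grid frequencies
#' (4.0, 4.5, ..., 7.5); 8.0 Hz counts as alpha.
#'
#' @param delta,theta,alpha two-element numeric ranges.
#' @return A list of class `band_scheme`.
#' @export
band_scheme <- function(delta = c(2, 4), theta = c(4, 8), alpha = c(8, 12)) {
  structure(list(delta = delta, theta = theta, alpha = alpha),
            class = "band_scheme")
}

band_of <- function(freqs, bands = band_scheme()) {
  out <- rep("other", length(freqs))
  out[freqs >= bands$delta[1] & freqs < bands$delta[2]] <- "delta"
  out[freqs >= bands$theta[1] & freqs < bands$theta[2]] <- "theta"
  out[freqs >= bands$alpha[1] & freqs <= bands$alpha[2]] <- "alpha"
  out
}

theta_candidates <- function(bands = band_scheme(), step = 0.5) {
  seq(bands$theta[1], bands$theta[2] - step, by = step)
}

#' Time-window x electrode peak-frequency matrix
#'
#' For every analysis window and electrode, the ERSP is reduced over the
#' window's time points per frequency (mean by default) and the frequency
#' with the highest value on the analysis grid is stored, together with that
#' value.  Argmax ties break toward the lower frequency.  With the default
#' 19 windows and 6 centroparietal electrodes this is the 114-cell matrix.
#'
#' @param ersp an `eeg_ersp` from [ersp()].
#' @param windows data frame from [make_time_windows()].
#' @param electrodes channel labels to include.
#' @param window_stat `"mean"` (default) or `"max"`: the within-window
#'   reduction over time samples before the argmax over frequency.
#' @return A `peak_matrix`: `peak_freq` and `peak_ersp` (windows x
#'   electrodes matrices), `windows`, `electrodes`, `freqs_hz`.
#' @export
peak_matrix <- function(ersp, windows = make_time_windows(),
                        electrodes = c("Cz", "C3", "C4", "Pz", "P3", "P4"),
                        window_stat = c("mean", "max")) {
  stopifnot(inherits(ersp, "eeg_ersp"))
  window_stat <- match.arg(window_stat)
  ei <- match(electrodes, ersp$channels)
  if (anyNA(ei))
    stop_itfx("electrodes not in the ERSP map: ",
              paste(electrodes[is.na(ei)], collapse = ", "),
              "; available: ", paste(ersp$channels, collapse = ", "),
              class = "itfx_data_error")
  nw <- nrow(windows); ne <- length(electrodes)
  pf <- matrix(NA_real_, nw, ne, dimnames = list(NULL, electrodes))
  pe <- matrix(NA_real_, nw, ne, dimnames = list(NULL, electrodes))
  stat <- if (window_stat == "mean") rowMeans else function(m) apply(m, 1, max)
  for (w in seq_len(nw)) {
    tsel <- ersp$times_ms >= windows$start_ms[w] & ersp$times_ms < windows$end_ms[w]
    if (!any(tsel))
      stop_itfx("window ", windows$start_ms[w], "-", windows$end_ms[w],
                " ms contains no ERSP samples", class = "itfx_parameter_error")
    for (e in seq_len(ne)) {
      sub <- ersp$ratio[ei[e], , tsel, drop = FALSE]     # 1 x freqs x times
      prof <- stat(matrix(sub, nrow = dim(sub)[2]))
      k <- which.max(prof)  # first maximum = lowest frequency on ties
      pf[w, e] <- ersp$freqs_hz[k]
      pe[w, e] <- prof[k]
    }
  }
  structure(list(peak_freq = pf, peak_ersp = pe, windows = windows,
                 electrodes = electrodes, freqs_hz = ersp$freqs_hz),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("<peak_matrix> %d windows x %d electrodes = %d cells\n",
              nrow(x$peak_freq), ncol(x$peak_freq), length(x$peak_freq)))
  invisible(x)
}

#' Export a peak matrix as TSV
#'
#' Rows are windows (first column `window_ms`), columns electrodes, values
#' peak frequencies in Hz.
#'
#' @param pm a `peak_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_matrix_tsv <- function(pm, path) {
  df <- data.frame(window_ms = sprintf("%g-%g", pm$windows$start_ms,
                                       pm$windows$end_ms),
                   pm$peak_freq, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Share of matrix cells peaking in each band
#'
#' @param pm a `peak_matrix`.
#' @param bands a [band_scheme()].
#' @return Named numeric vector (`delta`, `theta`, `alpha`, `other`) of
#'   percentages on the 0-100 scale; sums to 100.
#' @export
band_shares <- function(pm, bands = band_scheme()) {
  freqs <- as.vector(pm$peak_freq)
  if (length(freqs) == 0)
    stop_itfx("empty peak matrix", class = "itfx_data_error")
  b <- factor(band_of(freqs, bands), levels = c("delta", "theta", "alpha", "other"))
  counts <- table(b)
  out <- 100 * as.vector(counts) / sum(counts)
  names(out) <- names(counts)
  out
}

#' Extract the individual theta frequency from a peak matrix
#'
#' The ITF is the modal (most frequent) peak frequency among matrix cells
#' whose peak lies in the theta band; its reliability is the share of theta
#' cells carrying that mode.  A multimodal count distribution sets
#' `tie = TRUE` and is broken toward the candidate with the larger summed
#' ERSP over its cells (then toward the lower frequency); all tied candidates
#' are reported.  With no theta cells the ITF is undefined and the class is
#' `"none"`.
#'
#' @param pm a `peak_matrix`.
#' @param bands a [band_scheme()].
#' @return An `itf_result`: `itf_hz`, `reliability` (0-1),
#'   `reliability_class`, `band_shares`, `tie`, `tie_candidates_hz`,
#'   `fallback_used`, `n_theta_cells`, `n_cells`, `theta_counts`.
#' @export
extract_itf <- function(pm, bands = band_scheme()) {
  stopifnot(inherits(pm, "peak_matrix"))
  freqs <- as.vector(pm$peak_freq)
  if (length(freqs) == 0)
    stop_itfx("empty peak matrix", class = "itfx_data_error")
  shares <- band_shares(pm, bands)
  theta_sel <- band_of(freqs, bands) == "theta"
  n_theta <- sum(theta_sel)

  if (n_theta == 0) {
    return(itf_result(itf_hz = NA_real_, reliability = NA_real_,
                      reliability_class = "none", band_shares = shares,
                      tie = FALSE, tie_candidates_hz = numeric(),
                      fallback_used = FALSE, n_theta_cells = 0L,
                      n_cells = length(freqs), theta_counts = integer()))
  }

  tf <- freqs[theta_sel]
  te <- as.vector(pm$peak_ersp)[theta_sel]
  counts <- table(tf)
  cand <- as.numeric(names(counts))
  maxn <- max(counts)
  modal <- cand[counts == maxn]
  tie <- length(modal) > 1
  if (tie) {
    mass <- vapply(modal, function(f) sum(te[tf == f]), numeric(1))
    modal <- modal[order(-mass, modal)]
  }
  itf <- modal[1]
  reliability <- maxn / n_theta
  itf_result(itf_hz = itf, reliability = reliability,
             reliability_class = reliability_class(reliability),
             band_shares = shares, tie = tie,
             tie_candidates_hz = if (tie) modal else numeric(),
             fallback_used = FALSE, n_theta_cells = n_theta,
             n_cells = length(freqs),
             theta_counts = stats::setNames(as.integer(counts), names(counts)))
}

itf_result <- function(...) structure(list(...), class = "itf_result")

#' @export
print.itf_result <- function(x, ...) {
  if (is.na(x$itf_hz)) {
    cat("<itf_result> no theta-band peaks; ITF undefined (class: none)\n")
  } else {
    cat(sprintf("<itf_result> ITF = %.1f Hz (reliability %.2f, %s)%s%s\n",
                x$itf_hz, x$reliability, x$reliability_class,
                if (x$tie) sprintf(" [tie: %s Hz]",
                                   paste(x$tie_candidates_hz, collapse = ", ")) else "",
                if (x$fallback_used) " [PO7/PO8 fallback]" else ""))
  }
  cat(sprintf("  band shares: delta %.1f%% | theta %.1f%% | alpha %.1f%% | other %.1f%% (%d cells, %d theta)\n",
              x$band_shares["delta"], x$band_shares["theta"],
              x$band_shares["alpha"], x$band_shares["other"],
              x$n_cells, x$n_theta_cells))
  invisible(x)
}

#' Classify ITF reliability
#'
#' Five classes partitioning the unit interval: `none` `[0, 0.15)` (below the
#' 1-in-8 chance level for eight theta grid candidates), `unreliable`
#' `[0.15, 0.30]`, `reliable` `(0.30, 0.50]`, `highly_reliable`
#' `(0.50, 0.80]`, `singular` `(0.80, 1]`.
#'
#' @param reliability share in `[0, 1]` of theta cells carrying the ITF.
#' @return The class as a character scalar.
#' @export
#' @examples
#' reliability_class(0.70)  # "highly_reliable"
reliability_class <- function(reliability) {
  if (!is_scalar_num(reliability) || reliability < 0 || reliability > 1)
    stop_itfx("reliability must be a scalar in [0, 1]",
              class = "itfx_parameter_error")
  if (reliability < 0.15) "none"
  else if (reliability <= 0.30) "unreliable"
  else if (reliability <= 0.50) "reliable"
  else if (reliability <= 0.80) "highly_reliable"
  else "singular"
}

#' Extraction with parieto-occipital fallback
#'
#' Builds the primary peak matrix and, when its theta share falls below
#' `trigger_pct` (no prominent theta activity over the centroparietal
#' montage), appends the fallback electrodes (default PO7/PO8), rebuilds the
#' matrix and re-extracts, setting `fallback_used = TRUE`.  Missing fallback
#' electrodes produce a warning and the primary result.
#'
#' @param ersp an `eeg_ersp` containing (at least) the primary electrodes.
#' @param windows data frame from [make_time_windows()].
#' @param electrodes primary electrodes.
#' @param fallback_electrodes electrodes appended when triggered.
#' @param trigger_pct theta-share threshold (0-100); `0` disables fallback.
#' @param bands a [band_scheme()].
#' @param window_stat passed to [peak_matrix()].
#' @return An `itf_result` with `fallback_used` set accordingly and the
#'   matrix used attached as attribute `"peak_matrix"`.
#' @export
fallback_extract <- function(ersp, windows = make_time_windows(),
                             electrodes = c("Cz", "C3", "C4", "Pz", "P3", "P4"),
                             fallback_electrodes = c("PO7", "PO8"),
                             trigger_pct = 20, bands = band_scheme(),
                             window_stat = "mean") {
  pm <- peak_matrix(ersp, windows, electrodes, window_stat)
  res <- extract_itf(pm, bands)
  if (res$band_shares["theta"] < trigger_pct) {
    missing <- setdiff(fallback_electrodes, ersp$channels)
    if (length(missing)) {
      warning("fallback electrodes absent (", paste(missing, collapse = ", "),
              "); returning the primary extraction", call. = FALSE)
    } else {
      pm <- peak_matrix(ersp, windows, c(electrodes, fallback_electrodes),
                        window_stat)
      res <- extract_itf(pm, bands)
      res$fallback_used <- TRUE
    }
  }
  attr(res, "peak_matrix") <- pm
  res
}

#' Paired task-vs-rest theta-share contrast
#'
#' Two-sided Wilcoxon signed-rank test on paired per-subject theta shares
#' from the memory-task and resting-state analyses.
#'
#' @param am_theta_shares per-subject theta shares (0-100) from the task.
#' @param rs_theta_shares matched per-subject resting shares.
#' @return A list: `statistic`, `p_value`, `direction` (`"am_greater"`,
#'   `"rest_greater"`, or `"none"`), `median_difference`, `n`.
#' @export
compare_conditions <- function(am_theta_shares, rs_theta_shares) {
  if (length(am_theta_shares) != length(rs_theta_shares))
    stop_itfx("paired samples must have equal length", class = "itfx_data_error")
  n <- length(am_theta_shares)
  if (n < 5)
    stop_itfx("at least 5 pairs are required for the signed-rank test",
              class = "itfx_data_error")
  d <- am_theta_shares - rs_theta_shares
  if (all(d == 0))
    return(list(statistic = 0, p_value = 1, direction = "none",
                median_difference = 0, n = n))
  wt <- suppressWarnings(stats::wilcox.test(am_theta_shares, rs_theta_shares,
                                            paired = TRUE))
  md <- stats::median(d)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       direction = if (md > 0) "am_greater" else if (md < 0) "rest_greater" else "none",
       median_difference = md, n = n)
}
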