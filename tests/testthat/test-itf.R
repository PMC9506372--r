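# Window enumeration, peak matrix, band shares, modal extraction,
# reliability classes, fallback, and the paired contrast.

test_that("default window spec enumerates the 19 windows 250-350 ... 1150-1250", {
  w <- make_time_windows()
  expect_equal(nrow(w), 19)
  expect_equal(w$start_ms[1], 250)
  expect_equal(w$end_ms[1], 350)
  expect_equal(w$start_ms[19], 1150)
  expect_equal(w$end_ms[19], 1250)
  expect_equal(diff(w$start_ms), rep(50, 18))
})

test_that("window count follows (end-start-width)/step + 1", {
  expect_equal(nrow(make_time_windows(0, 100, 100, 50)), 1)
  expect_equal(nrow(make_time_windows(0, 300, 100, 50)), 5)
  expect_error(make_time_windows(0, 50, 100, 50), class = "itfx_parameter_error")
  for (seed in 1:25) {
    set.seed(seed)
    width <- sample(50:200, 1); step <- sample(10:100, 1)
    start <- sample(0:500, 1)
    end <- start + width + step * sample(0:20, 1)
    w <- make_time_windows(start, end, width, step)
    expect_equal(nrow(w), (end - start - width) / step + 1)
    expect_true(all(w$end_ms - w$start_ms == width))
    expect_true(all(w$end_ms <= end))
  }
})

test_that("a single dominant ridge fills all 114 default cells", {
  em <- ridge_ersp(5.5, ridge_window_ms = c(-1000, 2500))
  pm <- peak_matrix(em)
  expect_equal(length(pm$peak_freq), 114)
  expect_true(all(pm$peak_freq == 5.5))
})

test_that("peak_matrix matches the brute-force nested-loop oracle", {
  for (seed in 1:20) {
    em <- random_ersp(seed)
    w <- make_time_windows(0, 500, 150, 100)
    pm <- peak_matrix(em, windows = w, electrodes = c("CH2", "CH1"))
    oracle <- brute_force_peak_matrix(em, w, c("CH2", "CH1"))
    expect_identical(unname(pm$peak_freq), oracle$peak_freq)
    # cell values agree up to floating-point summation order
    expect_equal(unname(pm$peak_ersp), oracle$peak_ersp, tolerance = 1e-12)
  }
})

test_that("cell count equals windows x electrodes for random specs", {
  for (seed in 1:10) {
    set.seed(seed)
    em <- random_ersp(seed, n_channels = 4, n_times = 60)
    w <- make_time_windows(0, sample(c(600, 900, 1200), 1), 100, 50)
    els <- sample(em$channels, sample(2:4, 1))
    pm <- peak_matrix(em, windows = w, electrodes = els)
    expect_equal(length(pm$peak_freq), nrow(w) * length(els))
  }
})

test_that("argmax ties break toward the lower frequency", {
  em <- random_ersp(1, n_channels = 1, n_freqs = 5, n_times = 10)
  em$ratio[] <- 2  # all equal
  pm <- peak_matrix(em, windows = data.frame(start_ms = 0, end_ms = 250),
                    electrodes = "CH1")
  expect_equal(unname(pm$peak_freq[1, 1]), em$freqs_hz[1])
})

test_that("missing electrodes raise an error listing what is available", {
  em <- random_ersp(2)
  expect_error(peak_matrix(em, electrodes = c("CH1", "Pz")),
               "available.*CH1", class = "itfx_data_error")
})

test_that("band shares count half-open bands and sum to 100", {
  expect_equal(unname(band_shares(make_peak_matrix(rep(5, 114)))["theta"]), 100)
  bs <- band_shares(make_peak_matrix(c(rep(3, 57), rep(5, 57))))
  expect_equal(unname(bs[c("delta", "theta")]), c(50, 50))
  expect_equal(unname(band_shares(make_peak_matrix(8))["alpha"]), 100)
  expect_equal(unname(band_shares(make_peak_matrix(3.99))["delta"]), 100)
  expect_equal(unname(band_shares(make_peak_matrix(12.5))["other"]), 100)
  for (seed in 1:20) {
    set.seed(seed)
    freqs <- sample(seq(2, 15, 0.5), sample(5:114, 1), replace = TRUE)
    expect_equal(sum(band_shares(make_peak_matrix(freqs))), 100,
                 tolerance = 1e-9)
  }
})

test_that("the ITF is the modal theta frequency with its share as reliability", {
  pm <- make_peak_matrix(c(rep(4.5, 60), rep(5.0, 20), rep(9, 34)))
  res <- extract_itf(pm)
  expect_equal(res$itf_hz, 4.5)
  expect_equal(res$reliability, 0.75)
  expect_equal(res$n_theta_cells, 80)
  expect_false(res$tie)

  uni <- extract_itf(make_peak_matrix(rep(6, 114)))
  expect_equal(uni$reliability, 1)
  expect_identical(uni$reliability_class, "singular")

  none <- extract_itf(make_peak_matrix(rep(c(3, 9), 10)))
  expect_true(is.na(none$itf_hz))
  expect_identical(none$reliability_class, "none")
})

test_that("a double-mode matrix is flagged and resolved by summed ERSP mass", {
  # equal counts of 7.5 (early, stronger ERSP) and 5.5 (late, weaker)
  freqs <- c(rep(7.5, 40), rep(5.5, 40), rep(3, 34))
  ersps <- c(rep(3, 40), rep(2, 40), rep(1, 34))
  res <- extract_itf(make_peak_matrix(freqs, ersps))
  expect_true(res$tie)
  expect_equal(res$itf_hz, 7.5)
  expect_setequal(res$tie_candidates_hz, c(7.5, 5.5))
  # flipped mass resolves the other way
  res2 <- extract_itf(make_peak_matrix(freqs, rev(ersps)))
  expect_equal(res2$itf_hz, 5.5)
  # equal mass falls back to the lower frequency
  res3 <- extract_itf(make_peak_matrix(freqs, rep(1, 114)))
  expect_equal(res3$itf_hz, 5.5)
})

test_that("extraction is invariant under permutation of matrix cells", {
  set.seed(42)
  freqs <- sample(seq(2, 15, 0.5), 114, replace = TRUE)
  ersps <- rexp(114) + 1
  base <- extract_itf(make_peak_matrix(freqs, ersps))
  for (i in 1:10) {
    p <- sample(114)
    out <- extract_itf(make_peak_matrix(freqs[p], ersps[p]))
    expect_equal(out$itf_hz, base$itf_hz)
    expect_equal(out$reliability, base$reliability)
    expect_equal(out$band_shares, base$band_shares)
  }
})

test_that("reliability classes partition [0,1] with the stated boundaries", {
  grid <- c(0, 1e-9, seq(0.001, 1, by = 0.001))
  cls <- vapply(grid, reliability_class, "")
  expect_true(all(cls %in% c("none", "unreliable", "reliable",
                             "highly_reliable", "singular")))
  expect_identical(reliability_class(0.70), "highly_reliable")
  expect_identical(reliability_class(1.0), "singular")
  expect_identical(reliability_class(0.125), "none")
  expect_identical(reliability_class(0.15), "unreliable")
  expect_identical(reliability_class(0.30), "unreliable")
  expect_identical(reliability_class(0.31), "reliable")
  expect_identical(reliability_class(0.50), "reliable")
  expect_identical(reliability_class(0.80), "highly_reliable")
  expect_identical(reliability_class(0.81), "singular")
  expect_error(reliability_class(1.2), class = "itfx_parameter_error")
  expect_error(reliability_class(-0.1), class = "itfx_parameter_error")
})

test_that("fallback rebuilds the matrix with PO7/PO8 when theta is absent", {
  channels <- c("Cz", "C3", "C4", "Pz", "P3", "P4", "PO7", "PO8")
  # primary electrodes carry a delta ridge; PO7/PO8 a clean 6 Hz ridge
  em <- ridge_ersp(3, height = 3, channels = channels,
                   ridge_channels = c("Cz", "C3", "C4", "Pz", "P3", "P4"))
  fi <- match(6, em$freqs_hz)
  tsel <- em$times_ms >= 250 & em$times_ms < 1250
  em$ratio[7:8, fi, tsel] <- 5
  res <- fallback_extract(em)
  expect_true(res$fallback_used)
  expect_equal(res$itf_hz, 6)
  expect_equal(ncol(attr(res, "peak_matrix")$peak_freq), 8)

  # strong primary theta: no fallback
  em2 <- ridge_ersp(5.5, channels = channels)
  res2 <- fallback_extract(em2)
  expect_false(res2$fallback_used)

  # trigger 0 disables fallback even with zero theta share
  res3 <- fallback_extract(em, trigger_pct = 0)
  expect_false(res3$fallback_used)

  # absent fallback electrodes: warning + primary result
  em3 <- ridge_ersp(3, height = 3)
  expect_warning(res4 <- fallback_extract(em3), "absent")
  expect_false(res4$fallback_used)
})

test_that("paired theta-share contrast behaves like a signed-rank test", {
  res <- compare_conditions(rep(60, 10), rep(30, 10))
  expect_lt(res$p_value, 0.05)
  expect_identical(res$direction, "am_greater")

  same <- compare_conditions(1:8, 1:8)
  expect_equal(same$p_value, 1)
  expect_identical(same$direction, "none")

  set.seed(6)
  a <- runif(12, 30, 70); b <- runif(12, 20, 60)
  fwd <- compare_conditions(a, b)
  rev_ <- compare_conditions(b, a)
  expect_equal(fwd$p_value, rev_$p_value)
  expect_identical(rev_$direction,
                   if (fwd$direction == "am_greater") "rest_greater" else fwd$direction)

  expect_error(compare_conditions(1:4, 2:5), class = "itfx_data_error")
  expect_error(compare_conditions(1:5, 1:6), class = "itfx_data_error")
})
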