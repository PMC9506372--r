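# Recording IO, epoching, subsequent-memory labeling, resting segmentation,
# and the behavioral summary.

test_that("EDF round trip preserves fs, labels, and data to quantization", {
  set.seed(3)
  rec <- eeg_recording(matrix(rnorm(20 * 1000, sd = 20), nrow = 20),
                       fs = 500, channel_labels = itfx:::SIM_CHANNELS)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path)  # auto-detected as EDF
  expect_equal(back$fs, 500)
  expect_length(back$channel_labels, 20)
  expect_identical(back$channel_labels, rec$channel_labels)
  tol <- max(abs(rec$data)) / 32767
  expect_lt(max(abs(back$data - rec$data)), 2 * tol)
})

test_that("fixture container round-trips data, labels, and tables", {
  rec <- eeg_recording(matrix(sin(seq_len(800) / 10), nrow = 2), fs = 250,
                       channel_labels = c("Cz", "Pz"))
  tk <- toy_task(3)
  path <- withr::local_tempfile(fileext = ".json")
  write_fixture(rec, path, events = tk$events, behavior = tk$behavior)
  back <- read_fixture(path)
  expect_lt(max(abs(back$recording$data - rec$data)), 1e-6)
  expect_equal(back$recording$fs, 250)
  expect_identical(back$recording$channel_labels, c("Cz", "Pz"))
  expect_equal(back$events$pair_id, tk$events$pair_id)
  expect_equal(back$behavior$response, tk$behavior$response)

  zero <- eeg_recording(matrix(0, 1, 100), fs = 100, channel_labels = "Cz")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_fixture(zero, p2)
  expect_true(all(read_recording(p2, format = "fixture")$data == 0))
})

test_that("recording constructor enforces its invariants", {
  expect_error(read_recording("no/such/file.edf"), class = "itfx_io_error")
  expect_error(eeg_recording(matrix(0, 0, 10), 500, character()),
               class = "itfx_format_error")
  expect_error(eeg_recording(matrix(0, 2, 10), 500, c("Cz", "Cz")),
               class = "itfx_format_error")
  expect_warning(eeg_recording(matrix(0, 2, 10), 500, c("Cz", "XX9")),
                 "XX9")
  # case-insensitive canonicalization onto 10-10 names
  rec <- eeg_recording(matrix(0, 2, 10), 500, c("CZ", "po7"))
  expect_identical(rec$channel_labels, c("Cz", "PO7"))
})

test_that("subsequent-memory labeling follows recognition accuracy", {
  tk <- toy_task(4, responses_old = c("old", "recombined", "old", NA))
  lab <- label_epochs(tk$events, tk$behavior)
  expect_identical(lab$label, c("successful", "unsuccessful", "successful",
                                "unlabeled"))
  # recombined recognition trials contribute no label: flipping all their
  # responses changes nothing (exhaustive on the toy task)
  tk2 <- tk
  tk2$behavior$response[tk2$behavior$truth == "recombined"] <- "old"
  expect_identical(label_epochs(tk2$events, tk2$behavior)$label, lab$label)
  # an encoding pair never probed intact stays unlabeled
  tk3 <- toy_task(3)
  tk3$events <- tk3$events[tk3$events$pair_id != "P2" |
                             tk3$events$block == "encoding", ]
  tk3$behavior <- tk3$behavior[tk3$behavior$trial_id %in% tk3$events$trial_id, ]
  expect_identical(label_epochs(tk3$events, tk3$behavior)$label[2], "unlabeled")
})

test_that("duplicate intact-pair mapping is a data error", {
  tk <- toy_task(3)
  tk$events$pair_id[tk$events$trial_id == "R2"] <- "P1"
  tk$behavior <- tk$behavior[tk$behavior$trial_id != "R2", ]
  tk$behavior <- rbind(tk$behavior,
                       data.frame(trial_id = "R2", truth = "old", response = "old"))
  expect_error(label_epochs(tk$events, tk$behavior), class = "itfx_data_error")
})

test_that("label partition: successful + unsuccessful + unlabeled = total", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:10, 1)
    resp <- sample(c("old", "recombined", NA), n, replace = TRUE)
    lab <- label_epochs(toy_task(n, resp)$events, toy_task(n, resp)$behavior)
    expect_equal(sum(lab$label %in% c("successful", "unsuccessful", "unlabeled")),
                 n)
  }
})

test_that("epoch sample count is round((t1-t0)*fs/1000) for common rates", {
  for (fs in c(250, 500, 1000)) {
    ep <- make_epochs(list(function(t) sin(2 * pi * 5 * t)), n_trials = 2,
                      fs = fs)
    expect_equal(dim(ep$data)[3], round(3500 * fs / 1000))
    expect_equal(ep$times_ms[1], -1000)
  }
})

test_that("baseline correction zeroes constants and is idempotent", {
  ep <- make_epochs(list(function(t) rep(5, length(t))), n_trials = 3)
  expect_lt(max(abs(ep$data)), 1e-12)
  ep2 <- make_epochs(list(function(t) rnorm(length(t))), n_trials = 3)
  expect_equal(baseline_correct(ep2)$data, ep2$data, tolerance = 1e-12)
})

test_that("42 encoding onsets at 500 Hz give 42 x 1750-sample epochs", {
  set.seed(9)
  rec <- eeg_recording(matrix(rnorm(170 * 500), nrow = 1), 500, "Cz")
  ev <- data.frame(onset_ms = seq(2000, by = 3800, length.out = 42))
  ep <- epoch(rec, ev)
  expect_equal(dim(ep$data), c(42, 1, 1750))
  expect_false(any(ep$labels == "rejected"))
})

test_that("an epoch running past the recording end is rejected, others kept", {
  rec <- eeg_recording(matrix(rnorm(10 * 500), nrow = 1), 500, "Cz")
  ev <- data.frame(onset_ms = c(2000, 10000 - 300))  # 2nd needs 2500 ms more
  ep <- epoch(rec, ev)
  expect_identical(ep$labels, c("unlabeled", "rejected"))
  expect_true(all(is.finite(ep$data[1, , ])))
  expect_true(all(is.na(ep$data[2, , ])))
  expect_match(ep$log, "exceeds recording bounds")
})

test_that("resting segmentation yields floor(duration/3500ms) pseudo-epochs", {
  rec180 <- eeg_recording(matrix(rnorm(180 * 500), nrow = 1), 500, "Cz")
  expect_equal(dim(segment_resting(rec180)$data)[1], 51)
  rec1 <- eeg_recording(matrix(rnorm(1750), nrow = 1), 500, "Cz")
  ep1 <- segment_resting(rec1)
  expect_equal(dim(ep1$data)[1], 1)
  expect_false(anyNA(ep1$data))
  rec_short <- eeg_recording(matrix(rnorm(1749), nrow = 1), 500, "Cz")
  expect_error(segment_resting(rec_short), class = "itfx_data_error")
})

test_that("resting pseudo-onsets sit at the end of the first second", {
  rec <- eeg_recording(matrix(rnorm(12 * 500), nrow = 1), 500, "Cz")
  ep <- segment_resting(rec)
  expect_equal(ep$trial_info$onset_ms, c(1000, 4500, 8000))
  expect_equal(ep$t0_ms, -1000)
  expect_equal(ep$t1_ms, 2500)
  expect_true(all(ep$labels == "successful"))
})

test_that("behavior summary reports hit/CR/overall percentages", {
  perfect <- data.frame(trial_id = paste0("R", 1:84),
                        truth = rep(c("old", "recombined"), each = 42),
                        response = rep(c("old", "recombined"), each = 42))
  s <- summarize_behavior(perfect)
  expect_equal(c(s$overall_pct, s$hits_pct, s$correct_rejections_pct),
               c(100, 100, 100))

  part <- perfect
  part$response[1:42] <- c(rep("old", 25), rep("recombined", 17))
  expect_equal(summarize_behavior(part)$hits_pct, 100 * 25 / 42,
               tolerance = 1e-12)

  small <- data.frame(trial_id = paste0("R", 1:4),
                      truth = c("old", "old", "recombined", "recombined"),
                      response = c("old", "recombined", "recombined", "recombined"))
  expect_equal(summarize_behavior(small)$overall_pct, 75)
  expect_error(summarize_behavior(small[0, ]), class = "itfx_data_error")
})
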