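test_that("voltage tables round-trip at full float precision", {
  set.seed(11)
  rec <- raw_recording(rnorm(1024) * 50, rnorm(1024) * 20, 256, "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_voltage_table(rec, path)
  back <- read_voltage_table(path, 256)
  expect_identical(back$eeg, rec$eeg)
  expect_identical(back$emg, rec$emg)
  expect_equal(back$sample_rate_hz, 256)

  # tab-delimited, no header
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_voltage_table(rec, path2, sep = "\t", header = FALSE)
  back2 <- read_voltage_table(path2, 256)
  expect_identical(back2$eeg, rec$eeg)
})

test_that("non-conforming voltage files are rejected with the offending line", {
  path <- withr::local_tempfile()
  writeLines(c("1.0,2.0", "3.0,oops", "5.0,6.0"), path)
  expect_error(read_voltage_table(path, 256), "line 2")
  expect_error(read_voltage_table(path, 256), "non-numeric")

  path3 <- withr::local_tempfile()
  writeLines(c("1.0,2.0,3.0"), path3)
  expect_error(read_voltage_table(path3, 256), "3 value columns")

  path1 <- withr::local_tempfile()
  writeLines(c("1.0"), path1)
  expect_error(read_voltage_table(path1, 256), "1 value columns")

  expect_error(read_voltage_table(tempfile(), 256), "not found")
})

test_that("recording invariants are enforced", {
  expect_error(raw_recording(1:10, 1:9, 256), "identical length")
  expect_error(raw_recording(1:10, 1:10, -1), "positive")
  expect_error(raw_recording(c(1, NA), c(1, 2), 256), "finite")
  expect_error(raw_recording(c(1, Inf), c(1, 2), 256), "finite")
})

test_that("stage labels parse with the W/N/R one-hot mapping and A fallback", {
  path <- withr::local_tempfile()
  writeLines(c("W", "N", "R", "M", "W extra-token", "", "  "), path)
  codes <- parse_stage_labels(path)
  expect_identical(codes, c("W", "N", "R", "A", "W"))

  oh <- stage_onehot(c("W", "N", "R", "A"))
  expect_identical(unname(oh), rbind(c(1L, 0L, 0L), c(0L, 1L, 0L),
                                     c(0L, 0L, 1L), c(1L, 1L, 1L)))
  # bijection on W/N/R
  expect_identical(onehot_to_stage(stage_onehot(c("R", "W", "N"))),
                   c("R", "W", "N"))

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_identical(parse_stage_labels(empty), character(0))
})

test_that("polyphase resampling preserves DC and in-band sinusoids", {
  # 500 -> 256 Hz on a constant signal: exact away from the filter edges
  rec <- raw_recording(rep(2.5, 5000), rep(-1.25, 5000), 500, "dc")
  out <- resample_recording(rec, 256)
  expect_equal(out$sample_rate_hz, 256)
  expect_equal(length(out$eeg), ceiling(5000 * 64 / 125))
  mid <- 100:2400
  expect_lt(max(abs(out$eeg[mid] - 2.5)), 1e-6)
  expect_lt(max(abs(out$emg[mid] + 1.25)), 1e-6)

  # 5 Hz sinusoid at 500 Hz keeps its spectral peak at 5 Hz after 500 -> 256
  x <- sin(2 * pi * 5 * (0:4999) / 500)
  y <- resample_polyphase(x, 64, 125)
  psd <- welch_psd(y[100:2400], fs = 256, nperseg = 512)
  expect_lt(abs(psd$frequency[which.max(psd$power)] - 5), 256 / 512 + 1e-9)

  # identity when target equals source
  expect_identical(resample_recording(rec, 500), rec)
  expect_error(resample_recording(rec, 1000), "exceeds")
})

test_that("epoching follows the 1024-sample half-open window contract", {
  set.seed(3)
  sig <- rnorm(4100)
  rec <- raw_recording(sig, sig * 2, 256, "seg")
  ep <- segment_into_epochs(rec, c("W", "N", "R", "A"))
  expect_equal(nrow(ep$eeg), 4L)
  expect_equal(ncol(ep$eeg), 1024L)
  # epoch i = samples [1024 i, 1024 (i+1)) and concatenation restores the prefix
  expect_identical(ep$eeg[2, ], sig[1025:2048])
  expect_identical(as.numeric(t(ep$eeg)), sig[1:4096])

  # exact division
  rec2 <- raw_recording(sig[1:4096], sig[1:4096], 256, "seg2")
  expect_equal(nrow(segment_into_epochs(rec2, c("W", "N", "R", "W"))$eeg), 4L)

  # misalignment beyond one epoch reports both counts
  expect_error(segment_into_epochs(rec2, rep("W", 10)),
               "4 complete epochs.*10 labels")

  # one extra label absorbed (trailing partial window tolerance)
  ep3 <- segment_into_epochs(rec2, rep("W", 5))
  expect_equal(nrow(ep3$eeg), 4L)

  # unlabelled inference path
  ep4 <- segment_into_epochs(rec, labels = NULL)
  expect_equal(nrow(ep4$eeg), 4L)
  expect_true(all(is.na(ep4$labels)))

  expect_error(segment_into_epochs(raw_recording(1:10, 1:10, 256), c("W")),
               "shorter than one")
  rec500 <- raw_recording(sig, sig, 500, "wrongrate")
  expect_error(segment_into_epochs(rec500, c("W")), "256 Hz")
})
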