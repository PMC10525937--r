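test_that("recording constructor enforces the modality contract", {
  r <- toy_recording(333, "robot")
  expect_s3_class(r, "recording")
  expect_equal(duration(r), 333 / 71.42857, tolerance = 1e-9)
  expect_error(recording(matrix(0, 10, 8), "S1", "LW", 1, "robot"),
               class = "locomode_channel_mismatch")
  bad <- matrix(0, 10, 7); bad[3, 2] <- NA
  expect_error(recording(bad, "S1", "LW", 1, "robot"),
               class = "locomode_missing_value")
  expect_error(recording(matrix(0, 10, 7), "S1", "XX", 1, "robot"),
               class = "locomode_bad_label")
})

test_that("CSV round-trip reproduces samples bit-identically", {
  set.seed(7)
  r <- toy_recording(200, "emg", chan1 = rnorm(200) * exp(rnorm(200, 0, 4)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(r, path)
  r2 <- read_recording(path, list(subject_id = "S1", activity = "LW",
                                  trial_index = 1, modality = "emg"))
  expect_identical(r2$samples, r$samples)
  expect_identical(r2$channel_names, r$channel_names)
})

test_that("read_recording raises distinct errors per failure mode", {
  meta <- list(subject_id = "S1", activity = "LW", trial_index = 1,
               modality = "robot")
  expect_error(read_recording("nowhere.csv", meta),
               class = "locomode_missing_file")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(toy_recording(20, "emg"), path)  # 8 columns
  expect_error(read_recording(path, meta), class = "locomode_channel_mismatch")
  writeLines(c(paste(paste0("c", 1:7), collapse = ","),
               paste(c("1", "x", rep("3", 5)), collapse = ",")), path)
  expect_error(read_recording(path, meta), class = "locomode_non_numeric")
  writeLines(c(paste(paste0("c", 1:7), collapse = ","),
               paste(c("1", "", rep("3", 5)), collapse = ",")), path)
  expect_error(read_recording(path, meta), class = "locomode_missing_value")
})

test_that("normalisation stats compose extrema across recordings", {
  r1 <- toy_recording(10, chan1 = seq(-3, 5, length.out = 10))
  r2 <- toy_recording(10, chan1 = seq(0, 7, length.out = 10))
  st <- compute_normalization_stats(list(r1, r2))
  expect_equal(unname(st$stats$robot$min[1]), -3)
  expect_equal(unname(st$stats$robot$max[1]), 7)
  single <- compute_normalization_stats(list(r1))
  expect_equal(unname(single$stats$robot$min[1]), -3)
  expect_equal(unname(single$stats$robot$max[1]), 5)
  const <- toy_recording(10, chan1 = rep(4, 10))
  stc <- compute_normalization_stats(list(const))
  expect_equal(unname(stc$stats$robot$min[1]), 4)
  expect_equal(unname(stc$stats$robot$max[1]), 4)
  expect_error(compute_normalization_stats(list()),
               class = "locomode_empty_input")
})

test_that("normalisation maps to [-1, 1] with endpoint/midpoint/degenerate rules", {
  r <- toy_recording(11, chan1 = seq(2, 12, by = 1))
  st <- compute_normalization_stats(list(r))
  z <- apply_normalization(r, st)
  expect_equal(unname(z$samples[1, 1]), -1)     # x = min
  expect_equal(unname(z$samples[11, 1]), 1)     # x = max
  expect_equal(unname(z$samples[6, 1]), 0)      # midpoint
  expect_true(all(z$samples >= -1 & z$samples <= 1))
  # per-channel extrema are exactly +-1 for non-degenerate channels
  expect_equal(unname(apply(z$samples, 2, min)), rep(-1, 7))
  expect_equal(unname(apply(z$samples, 2, max)), rep(1, 7))
  # constant channel maps to 0
  const <- toy_recording(10, chan1 = rep(4, 10))
  zc <- apply_normalization(const, compute_normalization_stats(list(const)))
  expect_true(all(zc$samples[, 1] == 0))
  # out-of-range values are clipped
  wide <- toy_recording(10, chan1 = seq(-100, 100, length.out = 10))
  zw <- apply_normalization(wide, st)
  expect_true(all(zw$samples[, 1] >= -1 & zw$samples[, 1] <= 1))
  expect_error(apply_normalization(toy_recording(10, "emg"), st),
               class = "locomode_missing_stats")
})

test_that("normalisation is affine per channel between the endpoints", {
  set.seed(1)
  v <- runif(40, -5, 9)
  r <- toy_recording(40, chan1 = v)
  st <- compute_normalization_stats(list(r))
  z <- apply_normalization(r, st)
  expect_equal(z$samples[, 1], 2 * (v - min(v)) / (max(v) - min(v)) - 1)
})

test_that("manifest round-trips and rejects duplicate keys", {
  entries <- data.frame(file = c("a.csv", "b.csv"),
                        subject_id = c("S1", "S1"),
                        activity = c("LW", "SA"), trial_index = c(1, 1),
                        modality = c("robot", "robot"),
                        stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(entries, path)
  back <- read_manifest(path)
  expect_equal(back$file, entries$file)
  dup <- entries; dup$activity <- c("LW", "LW")
  expect_error(write_manifest(dup, path), class = "locomode_duplicate_entry")
})
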