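# Brute-force oracle: enumerate valid start indices directly.
brute_count <- function(L, W, s) {
  n <- 0L
  st <- 0
  while (st + W <= L) { n <- n + 1L; st <- st + s }
  n
}

test_that("window lengths match the 1.76 s protocol at both rates", {
  expect_identical(window_length(2000, 1.76), 3520L)
  expect_identical(window_length(71.42857, 1.76), 125L)
  expect_identical(window_length(100, 1.0), 100L)
  expect_error(window_length(-1, 1), class = "locomode_bad_argument")
})

test_that("window counts agree with brute-force start enumeration", {
  # printed-protocol case: robot trial of 333 samples, W = 125, step 12
  r <- toy_recording(333, "robot")
  ws <- make_windows(r)
  expect_identical(n_windows(ws), 18L)
  expect_equal(ws$start_index, seq(0, 204, by = 12))
  # exact-length and too-short trials
  expect_identical(n_windows(make_windows(toy_recording(125, "robot"))), 1L)
  expect_warning(ws0 <- make_windows(toy_recording(3519, "emg")),
                 "0 windows")
  expect_identical(n_windows(ws0), 0L)
  # randomised agreement with the enumeration oracle
  set.seed(42)
  for (i in 1:100) {
    W <- sample(5:200, 1)
    L <- W + sample(0:500, 1)
    overlap <- runif(1, 0, 0.95)
    s <- max(1, floor(W - W * overlap + 1e-9))
    r <- recording(matrix(rnorm(L * 7), L, 7), "S1", "LW", 1, "robot")
    ws <- suppressWarnings(make_windows(r, window_seconds = W / 71.42857,
                                        overlap_ratio = overlap))
    expect_identical(n_windows(ws), brute_count(L, W, s))
  }
})

test_that("windows are contiguous slices of the recording", {
  r <- toy_recording(333, "robot", chan1 = rnorm(333))
  ws <- make_windows(r)
  for (i in c(1, 7, 18)) {
    st <- ws$start_index[i]
    expect_equal(ws$windows[i, , ], r$samples[(st + 1):(st + 125), ],
                 ignore_attr = TRUE)
  }
})

test_that("group split honours the 8:1:1 ratio and determinism", {
  roster500 <- sprintf("P%03d", 1:500)
  sp <- group_split(roster500, seed = 9)
  expect_length(sp$train_subjects, 400)
  expect_length(sp$val_subjects, 50)
  expect_length(sp$test_subjects, 50)
  expect_length(intersect(sp$train_subjects, sp$val_subjects), 0)
  expect_length(intersect(sp$train_subjects, sp$test_subjects), 0)
  expect_length(intersect(sp$val_subjects, sp$test_subjects), 0)
  expect_setequal(c(sp$train_subjects, sp$val_subjects, sp$test_subjects),
                  roster500)
  sp10 <- group_split(sprintf("P%d", 1:10), seed = 1)
  expect_equal(lengths(sp10[1:3], use.names = FALSE), c(8L, 1L, 1L))
  expect_identical(group_split(roster500, seed = 9), sp)
  expect_false(identical(group_split(roster500, seed = 10), sp))
  expect_error(group_split(c("a", "b")), class = "locomode_bad_argument")
})

test_that("split spec JSON round-trips", {
  sp <- group_split(sprintf("P%d", 1:20), seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_split_spec(sp, path)
  expect_equal(read_split_spec(path)$val_subjects, sp$val_subjects)
})

test_that("assembled splits conserve windows and never share subjects", {
  splits <- segmented_robot(n_subjects = 6)
  total <- sum(splits$label_counts)
  expect_equal(n_windows(splits$train$robot) + n_windows(splits$val$robot) +
                 n_windows(splits$test$robot), total)
  subj <- list(train = unique(splits$train$robot$subject_ids),
               val = unique(splits$val$robot$subject_ids),
               test = unique(splits$test$robot$subject_ids))
  expect_length(intersect(subj$train, subj$val), 0)
  expect_length(intersect(subj$train, subj$test), 0)
  expect_length(intersect(subj$val, subj$test), 0)
  # windows of one subject land in exactly one split
  expect_true(all(table(unlist(subj)) == 1))
  expect_error(
    assemble_windows(group_split(sprintf("Q%d", 1:5)),
                     list(make_windows(toy_recording(333)))),
    class = "locomode_subject_unassigned")
})

test_that("paired assembly keeps the two modalities time-aligned", {
  cfg <- gaitsim_config(n_subjects = 3, seed = 5)
  recs <- simulate_recordings(cfg)
  roster <- unique(vapply(recs, `[[`, "", "subject_id"))
  split <- group_split(roster, seed = 1)
  stats <- compute_normalization_stats(
    Filter(function(r) r$subject_id %in% split$train_subjects, recs))
  step_s <- 1.76 * (1 - 0.9)
  sets <- lapply(lapply(recs, apply_normalization, stats = stats),
                 make_windows, anchor_step_s = step_s)
  splits <- assemble_windows(split, sets, paired = TRUE)
  for (sp in c("train", "val", "test")) {
    emg <- splits[[sp]]$emg
    rob <- splits[[sp]]$robot
    expect_identical(n_windows(emg), n_windows(rob))
    expect_identical(emg$trial_ids, rob$trial_ids)
    # same 1.76 s interval: start times differ by < one robot sample period
    dt <- abs(emg$start_index / 2000 - rob$start_index / 71.42857)
    expect_true(all(dt < 1 / 71.42857))
  }
})

test_that("window sets survive the binary container round-trip", {
  ws <- make_windows(toy_recording(333, chan1 = rnorm(333)))
  prefix <- file.path(withr::local_tempdir(), "ws")
  write_window_set(ws, prefix)
  back <- read_window_set(prefix)
  expect_equal(back$windows, ws$windows)
  expect_equal(back$labels, ws$labels)
  expect_equal(back$start_index, ws$start_index)
})
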