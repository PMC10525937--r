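# Overlapping sliding-window segmentation and subject-grouped 8:1:1 splits.

#' Window length in samples
#'
#' Number of samples covered by a window of `window_seconds` at a sampling
#' rate, rounded down: 1.76 s gives 3520 samples at 2000 Hz (EMG) and 125 at
#' 71.42857 Hz (exoskeleton).
#'
#' @param rate_hz Sampling rate (Hz), positive.
#' @param window_seconds Window duration (s), positive.
#' @return Integer window length (floor of the product).
#' @export
window_length <- function(rate_hz, window_seconds) {
  if (rate_hz <= 0 || window_seconds <= 0)
    abort_("locomode_bad_argument", "rate and window duration must be positive")
  # small epsilon so decimal fractions that are just below an integer in
  # binary (2000 * 1.76) land on it
  as.integer(floor(rate_hz * window_seconds + 1e-9))
}

# Step between successive window starts, in samples.
window_step <- function(W, overlap_ratio) {
  max(1L, as.integer(floor(W - W * overlap_ratio + 1e-9)))
}

#' Segment a recording into overlapping windows
#'
#' Cuts a (normalised) recording into fixed-length windows of
#' `window_seconds` whose consecutive starts are `floor(W * (1 - overlap))`
#' samples apart (W = window length). Every window lies fully inside the
#' trial; a trial shorter than one window yields zero windows with a warning.
#'
#' With `anchor_step_s` set, window starts are instead placed on the common
#' time grid `i * anchor_step_s` (rounded down to a sample index), which keeps
#' windows of two modalities of the same trial aligned to within one sample
#' period of the coarser stream; used by [assemble_windows()] for paired
#' multi-head data.
#'
#' @param r A [recording()].
#' @param window_seconds Window duration in seconds (default 1.76).
#' @param overlap_ratio Fraction of a window shared with its successor, in
#'   \[0, 1) (default 0.9).
#' @param anchor_step_s Optional start-time grid in seconds (see above).
#' @return An object of class `"window_set"`: `windows` (n x T x C array),
#'   `labels`, `subject_ids`, `trial_ids`, `start_index` and metadata.
#' @export
make_windows <- function(r, window_seconds = 1.76, overlap_ratio = 0.9,
                         anchor_step_s = NULL) {
  if (overlap_ratio < 0 || overlap_ratio >= 1)
    abort_("locomode_bad_argument", "overlap_ratio must be in [0, 1)")
  W <- window_length(r$sampling_rate_hz, window_seconds)
  L <- nrow(r$samples)
  if (is.null(anchor_step_s)) {
    s <- window_step(W, overlap_ratio)
    starts <- if (L >= W) seq.int(0L, L - W, by = s) else integer(0)
  } else {
    i <- 0L
    starts <- integer(0)
    repeat {
      st <- as.integer(floor(i * anchor_step_s * r$sampling_rate_hz + 1e-9))
      if (st + W > L) break
      starts <- c(starts, st)
      i <- i + 1L
    }
  }
  n <- length(starts)
  if (n == 0L)
    warning(sprintf("trial %s/%s/%d (%s): shorter than one window, 0 windows",
                    r$subject_id, r$activity, r$trial_index, r$modality))
  win <- array(0, dim = c(n, W, ncol(r$samples)))
  for (iw in seq_len(n))
    win[iw, , ] <- r$samples[(starts[iw] + 1L):(starts[iw] + W), ]
  trial_id <- paste(r$subject_id, r$activity, r$trial_index, sep = "/")
  structure(list(
    modality = r$modality,
    windows = win,
    labels = factor(rep(r$activity, n), levels = ACTIVITIES),
    subject_ids = rep(r$subject_id, n),
    trial_ids = rep(trial_id, n),
    start_index = starts,
    window_seconds = window_seconds,
    overlap_ratio = overlap_ratio,
    sampling_rate_hz = r$sampling_rate_hz
  ), class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set> %s: %d windows of %d x %d (%.2f s, overlap %.2f)\n",
              x$modality, d[1], d[2], d[3], x$window_seconds, x$overlap_ratio))
  invisible(x)
}

#' Number of windows in a set
#' @param ws A `"window_set"`.
#' @return Integer count.
#' @export
n_windows <- function(ws) dim(ws$windows)[1]

# Concatenate window sets of one modality (same T, C).
bind_window_sets <- function(sets) {
  sets <- Filter(function(s) n_windows(s) > 0L, sets)
  if (length(sets) == 0L) abort_("locomode_empty_input", "no windows to bind")
  d <- dim(sets[[1]]$windows)[-1]
  ntot <- sum(vapply(sets, n_windows, 0L))
  win <- array(0, dim = c(ntot, d))
  at <- 0L
  for (s in sets) {
    k <- n_windows(s)
    win[(at + 1L):(at + k), , ] <- s$windows
    at <- at + k
  }
  out <- sets[[1]]
  out$windows <- win
  out$labels <- factor(unlist(lapply(sets, function(s) as.character(s$labels))),
                       levels = ACTIVITIES)
  out$subject_ids <- unlist(lapply(sets, `[[`, "subject_ids"))
  out$trial_ids <- unlist(lapply(sets, `[[`, "trial_ids"))
  out$start_index <- unlist(lapply(sets, `[[`, "start_index"))
  out
}

# Subset a window set by index.
slice_window_set <- function(ws, idx) {
  ws$windows <- ws$windows[idx, , , drop = FALSE]
  ws$labels <- ws$labels[idx]
  ws$subject_ids <- ws$subject_ids[idx]
  ws$trial_ids <- ws$trial_ids[idx]
  ws$start_index <- ws$start_index[idx]
  ws
}

#' Subject-grouped train/validation/test split
#'
#' Partitions the subject roster into disjoint train/validation/test sets at
#' the given ratio by subject count, so that no subject contributes windows
#' to more than one split. Validation and test sizes are `round(share * N)`;
#' the remainder goes to the training set (500 subjects at 8:1:1 give
#' 400/50/50). Deterministic given the seed.
#'
#' @param roster Character vector of subject ids.
#' @param ratios Length-3 positive weights, default `c(8, 1, 1)`.
#' @param seed Integer seed for the subject shuffle.
#' @return An object of class `"split_spec"` with `train_subjects`,
#'   `val_subjects`, `test_subjects` and `seed`.
#' @export
group_split <- function(roster, ratios = c(8, 1, 1), seed = 1L) {
  roster <- unique(as.character(roster))
  if (length(roster) < 3L)
    abort_("locomode_bad_argument", "roster smaller than the number of splits")
  if (length(ratios) != 3L || any(ratios <= 0))
    abort_("locomode_bad_argument", "ratios must be 3 positive numbers")
  N <- length(roster)
  share <- ratios / sum(ratios)
  n_val <- max(1L, as.integer(round(share[2] * N)))
  n_test <- max(1L, as.integer(round(share[3] * N)))
  n_train <- N - n_val - n_test
  if (n_train < 1L)
    abort_("locomode_bad_argument", "roster too small for the requested ratio")
  perm <- local_seed(seed, sample(roster))
  structure(list(
    train_subjects = sort(perm[seq_len(n_train)]),
    val_subjects = sort(perm[n_train + seq_len(n_val)]),
    test_subjects = sort(perm[n_train + n_val + seq_len(n_test)]),
    seed = as.integer(seed)
  ), class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d / %d / %d subjects (seed %d)\n",
              length(x$train_subjects), length(x$val_subjects),
              length(x$test_subjects), x$seed))
  invisible(x)
}

#' Write a split spec as JSON
#' @param split A `"split_spec"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_spec <- function(split, path) write_json_(unclass(split), path)

#' Read a split spec from JSON
#' @param path JSON written by [write_split_spec()].
#' @return A `"split_spec"`.
#' @export
read_split_spec <- function(path) {
  structure(read_json_(path), class = "split_spec")
}

#' Assemble per-trial window sets into split datasets
#'
#' Groups per-trial window sets by modality, assigns every window to the
#' split containing its subject, and verifies the no-leakage contract (the
#' subject sets of the assembled splits are disjoint by construction; a
#' subject in no split is an error). When both modalities are present and
#' `paired = TRUE`, windows of the same trial are paired by ordinal and
#' trailing unmatched windows are dropped from both modalities, keeping the
#' two streams index-aligned for multi-head training.
#'
#' @param split A [group_split()] result.
#' @param windowsets List of per-trial `"window_set"` objects (one or both
#'   modalities).
#' @param paired Drop trailing unpaired windows so EMG/robot sets align
#'   (default `TRUE` when both modalities are present).
#' @return A list with elements `train`, `val`, `test` (each a named list of
#'   `"window_set"` per modality) and `label_counts` (per split x activity).
#' @export
assemble_windows <- function(split, windowsets, paired = NULL) {
  windowsets <- Filter(function(s) n_windows(s) > 0L, windowsets)
  mods <- unique(vapply(windowsets, `[[`, "", "modality"))
  if (is.null(paired)) paired <- length(mods) > 1L
  if (paired && length(mods) > 1L) {
    # per trial, truncate each modality's set to the common window count
    trials <- unique(vapply(windowsets, function(s) s$trial_ids[1], ""))
    for (tr in trials) {
      idx <- which(vapply(windowsets, function(s) s$trial_ids[1], "") == tr)
      k <- min(vapply(windowsets[idx], n_windows, 0L))
      for (i in idx)
        windowsets[[i]] <- slice_window_set(windowsets[[i]], seq_len(k))
    }
  }
  members <- list(train = split$train_subjects, val = split$val_subjects,
                  test = split$test_subjects)
  all_subj <- unique(unlist(lapply(windowsets, `[[`, "subject_ids")))
  missing <- setdiff(all_subj, unlist(members))
  if (length(missing))
    abort_("locomode_subject_unassigned",
           "subjects in no split: %s", paste(missing, collapse = ", "))
  out <- list()
  counts <- NULL
  for (sp in names(members)) {
    out[[sp]] <- list()
    for (m in mods) {
      sets <- Filter(function(s)
        s$modality == m && s$subject_ids[1] %in% members[[sp]], windowsets)
      if (length(sets) == 0L) next
      ws <- bind_window_sets(sets)
      out[[sp]][[m]] <- ws
      if (m == mods[1]) {
        tab <- table(ws$labels)
        counts <- rbind(counts, as.integer(tab))
      }
    }
  }
  if (!is.null(counts)) {
    rownames(counts) <- names(members)[seq_len(nrow(counts))]
    colnames(counts) <- ACTIVITIES
  }
  out$label_counts <- counts
  out
}

#' Persist a window set
#'
#' Writes the tensor as raw doubles alongside a JSON header recording shape,
#' element type, modality, labels and subjects, so a set can be reloaded
#' without re-segmenting.
#'
#' @param ws A `"window_set"`.
#' @param prefix Path prefix; `<prefix>.json` and `<prefix>.bin` are written.
#' @return `prefix`, invisibly.
#' @export
write_window_set <- function(ws, prefix) {
  header <- list(
    shape = dim(ws$windows), dtype = "float64", byte_order = "little",
    modality = ws$modality, labels = as.character(ws$labels),
    subject_ids = ws$subject_ids, trial_ids = ws$trial_ids,
    start_index = ws$start_index, window_seconds = ws$window_seconds,
    overlap_ratio = ws$overlap_ratio, sampling_rate_hz = ws$sampling_rate_hz,
    label_levels = ACTIVITIES)
  write_json_(header, paste0(prefix, ".json"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(ws$windows), con, size = 8L, endian = "little")
  invisible(prefix)
}

#' Load a persisted window set
#' @param prefix Path prefix used in [write_window_set()].
#' @return A `"window_set"`.
#' @export
read_window_set <- function(prefix) {
  h <- read_json_(paste0(prefix, ".json"))
  n <- prod(h$shape)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8L, endian = "little")
  structure(list(
    modality = h$modality,
    windows = array(v, dim = h$shape),
    labels = factor(h$labels, levels = h$label_levels),
    subject_ids = h$subject_ids,
    trial_ids = h$trial_ids,
    start_index = h$start_index,
    window_seconds = h$window_seconds,
    overlap_ratio = h$overlap_ratio,
    sampling_rate_hz = h$sampling_rate_hz
  ), class = "window_set")
}
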