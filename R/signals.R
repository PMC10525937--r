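# Domain types for multichannel gait recordings, on-disk I/O, and the
# train-split min-max normalisation applied before segmentation.

#' Locomotion-mode class labels
#'
#' The five locomotion modes recognised throughout the package: level-ground
#' walking (LW), stair ascent (SA), stair descent (SD), ramp ascent (RA) and
#' ramp descent (RD).
#' @export
ACTIVITIES <- c("LW", "SA", "SD", "RA", "RD")

#' Modality layout
#'
#' Channel layout and sampling rate for a sensing modality: surface EMG
#' (8 channels, VL/TA/BF/GAL of both legs, 2000 Hz) or the hip-exoskeleton
#' stream (7 channels: left/right hip angle in degrees, left/right angular
#' velocity in rpm, roll/pitch/yaw in degrees, 71.42857 Hz).
#'
#' @param modality `"emg"` or `"robot"`.
#' @return A list with `n_channels`, `rate_hz` and default `channel_names`.
#' @export
modality_info <- function(modality) {
  switch(match.arg(modality, c("emg", "robot")),
    emg = list(
      n_channels = 8L, rate_hz = 2000,
      channel_names = c("VL_L", "VL_R", "TA_L", "TA_R",
                        "BF_L", "BF_R", "GAL_L", "GAL_R")),
    robot = list(
      n_channels = 7L, rate_hz = 71.42857,
      channel_names = c("hip_angle_L", "hip_angle_R", "hip_vel_L",
                        "hip_vel_R", "roll", "pitch", "yaw"))
  )
}

#' Construct a recording
#'
#' A recording is one trial's multichannel signal plus its metadata. The
#' constructor enforces the modality contract (channel count and sampling
#' rate) and rejects missing or non-finite values.
#'
#' @param samples Numeric matrix, time in rows, channels in columns.
#' @param subject_id Subject identifier string.
#' @param activity One of [ACTIVITIES].
#' @param trial_index Integer in 1..3.
#' @param modality `"emg"` or `"robot"`.
#' @param channel_names Optional channel names; defaults to the modality's
#'   standard layout.
#' @return An object of class `"recording"`.
#' @export
recording <- function(samples, subject_id, activity, trial_index, modality,
                      channel_names = NULL) {
  info <- modality_info(modality)
  modality <- match.arg(modality, c("emg", "robot"))
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!activity %in% ACTIVITIES)
    abort_("locomode_bad_label", "unknown activity '%s'", activity)
  if (!trial_index %in% 1:3)
    abort_("locomode_bad_trial", "trial_index must be 1, 2 or 3")
  if (ncol(samples) != info$n_channels)
    abort_("locomode_channel_mismatch",
           "modality '%s' expects %d channels, got %d",
           modality, info$n_channels, ncol(samples))
  if (nrow(samples) < 1L)
    abort_("locomode_empty_recording", "recording has no samples")
  if (anyNA(samples))
    abort_("locomode_missing_value", "recording contains missing values")
  if (!all(is.finite(samples)))
    abort_("locomode_non_numeric", "recording contains non-finite values")
  channel_names <- channel_names %||% info$channel_names
  colnames(samples) <- channel_names
  structure(list(
    subject_id = as.character(subject_id),
    activity = activity,
    trial_index = as.integer(trial_index),
    modality = modality,
    sampling_rate_hz = info$rate_hz,
    channel_names = channel_names,
    samples = samples
  ), class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s, %s, trial %d, %s: %d x %d (%.3f s @ %g Hz)\n",
              x$subject_id, x$activity, x$trial_index, x$modality,
              nrow(x$samples), ncol(x$samples), duration(x), x$sampling_rate_hz))
  invisible(x)
}

#' Trial duration in seconds
#'
#' @param r A [recording()].
#' @return Row count divided by the sampling rate.
#' @export
duration <- function(r) nrow(r$samples) / r$sampling_rate_hz

#' Write a recording as CSV
#'
#' One sample per row, header row of channel names. Values are written in a
#' round-trippable representation so [read_recording()] reproduces the samples
#' bit-identically.
#'
#' @param r A [recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(r, path) {
  # %.17g guarantees the shortest representation that parses back to the
  # identical double, which fwrite's default 15 digits does not
  cells <- matrix(sprintf("%.17g", r$samples), nrow(r$samples))
  lines <- do.call(paste, c(split(cells, col(cells)), sep = ","))
  writeLines(c(paste(r$channel_names, collapse = ","), lines), path)
  invisible(path)
}

#' Read a recording from CSV
#'
#' @param path CSV file written by [write_recording()] (header of channel
#'   names, one sample per row).
#' @param meta Manifest entry: a list with `subject_id`, `activity`,
#'   `trial_index` and `modality`.
#' @return A [recording()].
#' @export
read_recording <- function(path, meta) {
  if (!file.exists(path))
    abort_("locomode_missing_file", "no such file: %s", path)
  dt <- data.table::fread(path, header = TRUE)
  m <- as.matrix(dt)
  if (!is.numeric(m))
    abort_("locomode_non_numeric", "non-numeric cells in %s", path)
  info <- modality_info(meta$modality)
  if (ncol(m) != info$n_channels)
    abort_("locomode_channel_mismatch",
           "%s: modality '%s' expects %d channels, file has %d",
           path, meta$modality, info$n_channels, ncol(m))
  if (anyNA(m))
    abort_("locomode_missing_value", "missing values in %s", path)
  recording(m, meta$subject_id, meta$activity, meta$trial_index,
            meta$modality, channel_names = colnames(m))
}

#' Write a dataset manifest
#'
#' The manifest is a JSON array of trial entries (file path, subject,
#' activity, trial index, modality, sampling rate, channel names). The
#' (subject, activity, trial, modality) key must be unique.
#'
#' @param entries A data.frame with columns `file`, `subject_id`, `activity`,
#'   `trial_index`, `modality`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path) {
  key <- with(entries, paste(subject_id, activity, trial_index, modality))
  if (anyDuplicated(key))
    abort_("locomode_duplicate_entry",
           "duplicate (subject, activity, trial, modality) in manifest")
  jsonlite::write_json(entries, path, dataframe = "rows", digits = NA,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read a dataset manifest
#' @param path Manifest JSON written by [write_manifest()].
#' @return A data.frame of trial entries.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    abort_("locomode_missing_file", "no such file: %s", path)
  as.data.frame(read_json_(path))
}

#' Per-channel min-max statistics from training recordings
#'
#' Computes, separately per modality, the global per-channel minimum and
#' maximum over all supplied recordings. By contract the input is the
#' training split only, so that normalisation of validation/test data uses no
#' information from those splits.
#'
#' @param train_recordings Non-empty list of [recording()]s.
#' @param provenance Free-text note on which split the stats came from.
#' @return An object of class `"norm_stats"`: per modality a list with
#'   `min` and `max` vectors (one entry per channel) and `channel_names`.
#' @export
compute_normalization_stats <- function(train_recordings,
                                        provenance = "train") {
  if (length(train_recordings) == 0L)
    abort_("locomode_empty_input", "no recordings supplied")
  out <- list()
  for (r in train_recordings) {
    stopifnot(inherits(r, "recording"))
    m <- r$modality
    lo <- apply(r$samples, 2L, min)
    hi <- apply(r$samples, 2L, max)
    if (is.null(out[[m]])) {
      out[[m]] <- list(min = lo, max = hi, channel_names = r$channel_names)
    } else {
      if (!identical(out[[m]]$channel_names, r$channel_names))
        abort_("locomode_mixed_layout",
               "recordings of modality '%s' have differing channel layouts", m)
      out[[m]]$min <- pmin(out[[m]]$min, lo)
      out[[m]]$max <- pmax(out[[m]]$max, hi)
    }
  }
  structure(list(stats = out, provenance = provenance), class = "norm_stats")
}

#' Normalise a recording to [-1, 1]
#'
#' Maps every value x to `2 * (x - min) / (max - min) - 1` with the
#' per-channel training-split statistics, clipping to \[-1, 1\] for values
#' outside the training range. Constant (degenerate) channels map to 0, the
#' centre of the target range.
#'
#' @param r A [recording()].
#' @param stats A [compute_normalization_stats()] result covering `r`'s
#'   modality.
#' @return The normalised [recording()].
#' @export
apply_normalization <- function(r, stats) {
  st <- stats$stats[[r$modality]]
  if (is.null(st))
    abort_("locomode_missing_stats",
           "no normalisation stats for modality '%s'", r$modality)
  rng <- st$max - st$min
  x <- r$samples
  for (j in seq_len(ncol(x))) {
    if (rng[j] == 0) {
      x[, j] <- 0
    } else {
      x[, j] <- pmin(1, pmax(-1, 2 * (x[, j] - st$min[j]) / rng[j] - 1))
    }
  }
  r$samples <- x
  r
}

#' Serialise normalisation statistics as JSON
#' @param stats A `"norm_stats"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normalization_stats <- function(stats, path) {
  write_json_(unclass(stats), path)
}

#' Read normalisation statistics from JSON
#' @param path JSON written by [write_normalization_stats()].
#' @return A `"norm_stats"` object.
#' @export
read_normalization_stats <- function(path) {
  x <- read_json_(path)
  structure(list(stats = x$stats, provenance = x$provenance),
            class = "norm_stats")
}
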