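# Shared fixture builders; everything is generated in code at test time.

# A recording with prescribed values in channel 1 and zeros elsewhere.
toy_recording <- function(n = 50, modality = "robot", subject = "S1",
                          activity = "LW", trial = 1, chan1 = NULL) {
  k <- modality_info(modality)$n_channels
  m <- matrix(0, n, k)
  m[, 1] <- chan1 %||% seq_len(n)
  for (j in 2:k) m[, j] <- sin(seq_len(n) / j)
  recording(m, subject, activity, trial, modality)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small segmented robot dataset from the simulator, grouped by subject.
segmented_robot <- function(n_subjects = 6, seed = 3, class_separation = 1,
                            split_seed = 1) {
  cfg <- gaitsim_config(n_subjects = n_subjects, seed = seed,
                        class_separation = class_separation)
  recs <- simulate_recordings(cfg, modalities = "robot")
  roster <- unique(vapply(recs, `[[`, "", "subject_id"))
  split <- group_split(roster, seed = split_seed)
  stats <- compute_normalization_stats(
    Filter(function(r) r$subject_id %in% split$train_subjects, recs))
  sets <- lapply(lapply(recs, apply_normalization, stats = stats),
                 make_windows)
  assemble_windows(split, sets)
}

# Random probability-free label pair over the activity set.
random_labels <- function(n) {
  list(truth = sample(ACTIVITIES, n, replace = TRUE),
       pred = sample(ACTIVITIES, n, replace = TRUE))
}
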