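# Seeded synthetic generator for multimodal gait recordings: hip-exoskeleton
# encoder/IMU channels built from a sinusoidal gait model, EMG channels as
# noise amplitude-modulated by periodic per-muscle burst envelopes. The
# generator's contract is structural fidelity (channels, rates, per-activity
# trial durations and gait-cycle periods, 3 trials x 5 activities) plus a
# controllable degree of between-activity separability; waveform realism is
# a non-goal.

# Per-activity defaults: trial durations (EMG row of the measurement-time
# table) and gait-cycle periods (left-heel-strike row of the cycle table).
.duration_defaults <- list(
  mean = c(LW = 4.81, SA = 4.65, SD = 4.60, RA = 4.90, RD = 4.34),
  sd   = c(LW = 1.52, SA = 1.12, SD = 1.10, RA = 1.36, RD = 1.30))
.cycle_defaults <- list(
  mean = c(LW = 1.40, SA = 1.57, SD = 1.51, RA = 1.93, RD = 1.62),
  sd   = c(LW = 0.33, SA = 0.40, SD = 0.32, RA = 0.47, RD = 0.48))

# Activity templates at full separation (class_separation = 1): hip-angle
# amplitude/offset (deg), pitch offset (deg, positive for ascents), stair
# step-ripple gain, and per-muscle burst phases (fraction of gait cycle) and
# gains for VL, TA, BF, GAL.
.templates <- list(
  hip_amp      = c(LW = 30, SA = 45, SD = 40, RA = 35, RD = 25),
  hip_offset   = c(LW = 5,  SA = 15, SD = 10, RA = 12, RD = 2),
  pitch_offset = c(LW = 0,  SA = 8,  SD = -8, RA = 5,  RD = -5),
  ripple_gain  = c(LW = 0,  SA = 3,  SD = 3,  RA = 0,  RD = 0),
  burst_phase = rbind(
    LW = c(0.05, 0.55, 0.45, 0.80), SA = c(0.15, 0.50, 0.35, 0.70),
    SD = c(0.30, 0.60, 0.55, 0.90), RA = c(0.10, 0.45, 0.40, 0.75),
    RD = c(0.25, 0.65, 0.50, 0.85)),
  burst_gain = rbind(
    LW = c(1.0, 0.8, 0.9, 1.0), SA = c(1.5, 0.7, 1.1, 1.3),
    SD = c(1.1, 1.2, 0.8, 0.9), RA = c(1.3, 0.9, 1.0, 1.2),
    RD = c(0.9, 1.1, 1.2, 0.8)),
  burst_width = 0.08)

#' Synthetic-dataset configuration
#'
#' Defines the conditions emulated by the generator: number of subjects,
#' three trials per activity, per-activity trial-duration and gait-cycle
#' distributions, the separation between activity templates, and sensor
#' noise. Durations follow truncated normals bounded below by one window
#' length (1.76 s) whose location is calibrated so the realised mean equals
#' the configured mean.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer master seed; every trial derives its own stream from
#'   it, so any subset of the dataset is reproducible in isolation.
#' @param class_separation Non-negative scale on the differences between
#'   activity templates (and between per-activity gait-period
#'   distributions). 1 is the calibrated default; 0 makes the five
#'   activities statistically indistinguishable.
#' @param noise_sd Exoskeleton sensor noise SD in degrees (clipped Gaussian,
#'   bounded at 3 SD), must be positive.
#' @param trials_per_activity Trials per subject and activity (default 3).
#' @param duration_mean_s,duration_sd_s Named per-activity duration
#'   parameters in seconds.
#' @param cycle_mean_s,cycle_sd_s Named per-activity gait-cycle parameters
#'   in seconds.
#' @return An object of class `"gaitsim_config"`.
#' @export
gaitsim_config <- function(n_subjects = 20L, seed = 1L, class_separation = 1,
                           noise_sd = 0.5, trials_per_activity = 3L,
                           duration_mean_s = .duration_defaults$mean,
                           duration_sd_s = .duration_defaults$sd,
                           cycle_mean_s = .cycle_defaults$mean,
                           cycle_sd_s = .cycle_defaults$sd) {
  if (noise_sd <= 0)
    abort_("locomode_bad_argument", "noise_sd must be positive")
  if (class_separation < 0)
    abort_("locomode_bad_argument", "class_separation must be >= 0")
  stopifnot(all(ACTIVITIES %in% names(duration_mean_s)),
            all(duration_sd_s >= 0), all(cycle_sd_s >= 0))
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects),
    seed = as.integer(seed),
    class_separation = class_separation,
    noise_sd = noise_sd,
    trials_per_activity = as.integer(trials_per_activity),
    duration_mean_s = duration_mean_s[ACTIVITIES],
    duration_sd_s = duration_sd_s[ACTIVITIES],
    cycle_mean_s = cycle_mean_s[ACTIVITIES],
    cycle_sd_s = cycle_sd_s[ACTIVITIES],
    min_duration_s = 1.76
  ), class = "gaitsim_config")
  # location parameters of the duration truncated normals, calibrated so the
  # truncated-distribution mean equals the configured mean
  cfg$duration_loc <- vapply(ACTIVITIES, function(a)
    calibrate_truncnorm_location(cfg$duration_mean_s[[a]],
                                 cfg$duration_sd_s[[a]],
                                 cfg$min_duration_s), 0)
  cfg
}

# Mean of Normal(m, sd) truncated below at `lower`.
truncnorm_mean <- function(m, sd, lower) {
  if (sd == 0) return(max(m, lower))
  a <- (lower - m) / sd
  m + sd * dnorm(a) / (1 - pnorm(a))
}

# Solve for the location m such that the lower-truncated normal has the
# requested mean.
calibrate_truncnorm_location <- function(target_mean, sd, lower) {
  if (sd == 0) return(target_mean)
  if (target_mean <= lower)
    abort_("locomode_bad_argument",
           "target mean %.3f not reachable with lower bound %.3f",
           target_mean, lower)
  uniroot(function(m) truncnorm_mean(m, sd, lower) - target_mean,
          lower = target_mean - 4 * sd, upper = target_mean + sd,
          tol = 1e-10)$root
}

# Draw from Normal(m, sd) truncated below at `lower` via inverse CDF.
rtruncnorm_lower <- function(n, m, sd, lower) {
  if (sd == 0) return(rep(max(m, lower), n))
  p0 <- pnorm((lower - m) / sd)
  qnorm(runif(n, p0, 1)) * sd + m
}

# Blend a per-activity parameter toward its across-activity mean:
# separation 1 returns the template values, 0 collapses them to the pooled
# value so activities are indistinguishable.
blend_ <- function(values, sep) {
  pooled <- mean(values)
  pooled + sep * (values - pooled)
}
blend_rows_ <- function(m, sep) {
  pooled <- colMeans(m)
  sweep(sweep(m, 2, pooled, "-") * sep, 2, pooled, "+")
}

# Subject-level traits (gait phase, amplitude factor), reproducible from the
# master seed and subject id alone.
subject_traits <- function(cfg, subject_id) {
  local_seed(hash31(cfg$seed, "subject", subject_id), {
    list(phase = runif(1, 0, 2 * pi),
         amp_factor = max(0.7, rnorm(1, 1, 0.05)))
  })
}

# Duration and gait period of one trial, reproducible in isolation. Drawn
# first in the trial's stream so duration summaries need not generate
# signals.
trial_plan <- function(cfg, subject_id, activity, trial_index) {
  sep <- cfg$class_separation
  cyc_m <- blend_(cfg$cycle_mean_s, sep)[[activity]]
  cyc_s <- blend_(cfg$cycle_sd_s, sep)[[activity]]
  local_seed(hash31(cfg$seed, "trial", subject_id, activity, trial_index), {
    list(duration = rtruncnorm_lower(1, cfg$duration_loc[[activity]],
                                     cfg$duration_sd_s[[activity]],
                                     cfg$min_duration_s),
         period = rtruncnorm_lower(1, cyc_m, cyc_s, 0.6))
  })
}

#' Simulate one trial
#'
#' Generates the time-aligned EMG and exoskeleton recordings of one trial.
#' Exoskeleton channels: left hip angle `offset + A sin(2 pi t / P + phi)`
#' (activity-dependent offset/amplitude, subject-dependent phase), right hip
#' angle in anti-phase, angular velocities as the analytic derivative
#' rescaled to rpm, small roll/yaw oscillations, and pitch offset positive
#' for ascents and negative for descents with a superimposed step ripple for
#' stairs. EMG channels are zero-mean Gaussian noise amplitude-modulated by
#' per-muscle periodic Gaussian-bump envelopes at activity-specific phases.
#' Deterministic given (subject, activity, trial, seed).
#'
#' @param subject_id Subject id string.
#' @param activity One of [ACTIVITIES].
#' @param trial_index Trial number.
#' @param cfg A [gaitsim_config()].
#' @param modalities Which modalities to materialise (both by default; the
#'   exoskeleton stream is identical either way).
#' @return Named list of [recording()]s (`emg` and/or `robot`).
#' @export
simulate_trial <- function(subject_id, activity, trial_index, cfg,
                           modalities = c("emg", "robot")) {
  if (!activity %in% ACTIVITIES)
    abort_("locomode_bad_label", "unknown activity '%s'", activity)
  modalities <- match.arg(modalities, several.ok = TRUE)
  sep <- cfg$class_separation
  plan <- trial_plan(cfg, subject_id, activity, trial_index)
  tr <- subject_traits(cfg, subject_id)
  amp <- blend_(.templates$hip_amp, sep)[[activity]] * tr$amp_factor
  off <- blend_(.templates$hip_offset, sep)[[activity]]
  pit <- blend_(.templates$pitch_offset, sep)[[activity]]
  rip <- blend_(.templates$ripple_gain, sep)[[activity]]
  bphase <- blend_rows_(.templates$burst_phase, sep)[activity, ]
  bgain <- blend_rows_(.templates$burst_gain, sep)[activity, ]
  P <- plan$period
  d <- plan$duration
  out <- list()
  local_seed(hash31(cfg$seed, "signal", subject_id, activity, trial_index), {
    clipn <- function(n, sd) pmin(3 * sd, pmax(-3 * sd, rnorm(n, 0, sd)))
    info_r <- modality_info("robot")
    nr <- max(1L, as.integer(floor(d * info_r$rate_hz)))
    t <- (seq_len(nr) - 1L) / info_r$rate_hz
    w <- 2 * pi / P
    hipL <- off + amp * sin(w * t + tr$phase) + clipn(nr, cfg$noise_sd)
    hipR <- off + amp * sin(w * t + tr$phase + pi) + clipn(nr, cfg$noise_sd)
    # deg/s -> rpm (1 rpm = 6 deg/s)
    velL <- amp * w * cos(w * t + tr$phase) / 6 + clipn(nr, cfg$noise_sd)
    velR <- amp * w * cos(w * t + tr$phase + pi) / 6 + clipn(nr, cfg$noise_sd)
    roll <- 1.5 * sin(w * t + tr$phase + pi / 3) + clipn(nr, cfg$noise_sd)
    pitch <- pit + 1.0 * sin(w * t + tr$phase + pi / 5) +
      rip * sin(2 * w * t + tr$phase) + clipn(nr, cfg$noise_sd)
    yaw <- 1.0 * sin(w * t / 2 + tr$phase) + clipn(nr, cfg$noise_sd)
    robot <- recording(cbind(hipL, hipR, velL, velR, roll, pitch, yaw),
                       subject_id, activity, trial_index, "robot")
    if ("robot" %in% modalities) out$robot <- robot
    if ("emg" %in% modalities) {
      info_e <- modality_info("emg")
      ne <- max(1L, as.integer(floor(d * info_e$rate_hz)))
      te <- (seq_len(ne) - 1L) / info_e$rate_hz
      cyc <- ((te / P) + tr$phase / (2 * pi)) %% 1
      wd <- .templates$burst_width
      ch <- matrix(0, ne, 8L)
      for (k in 1:4) {
        for (side in 0:1) {            # left, then right half a cycle later
          centre <- (bphase[k] + 0.5 * side) %% 1
          dd <- abs(cyc - centre)
          dd <- pmin(dd, 1 - dd)
          env <- 0.05 + bgain[k] * exp(-0.5 * (dd / wd)^2)
          ch[, 2L * (k - 1L) + side + 1L] <- env * rnorm(ne)
        }
      }
      # interleave as VL_L, VL_R, TA_L, TA_R, BF_L, BF_R, GAL_L, GAL_R
      out$emg <- recording(ch, subject_id, activity, trial_index, "emg")
    }
  })
  out[intersect(c("emg", "robot"), modalities)]
}

#' Draw the trial durations of a whole dataset
#'
#' Returns the per-trial durations and gait periods of the configured
#' dataset without materialising any signal, using exactly the draws
#' [simulate_trial()] would use. Useful for calibration summaries at full
#' study scale.
#'
#' @param cfg A [gaitsim_config()].
#' @return A data.frame with `subject_id`, `activity`, `trial_index`,
#'   `duration_s`, `period_s`.
#' @export
simulate_durations <- function(cfg) {
  subjects <- sprintf("S%04d", seq_len(cfg$n_subjects))
  grid <- expand.grid(trial_index = seq_len(cfg$trials_per_activity),
                      activity = ACTIVITIES, subject_id = subjects,
                      stringsAsFactors = FALSE)
  plans <- mapply(function(s, a, k) unlist(trial_plan(cfg, s, a, k)),
                  grid$subject_id, grid$activity, grid$trial_index)
  data.frame(subject_id = grid$subject_id, activity = grid$activity,
             trial_index = grid$trial_index,
             duration_s = plans["duration", ], period_s = plans["period", ],
             row.names = NULL)
}

#' Simulate a dataset in memory
#'
#' Generates all trials of the configured dataset as a list of recordings.
#'
#' @param cfg A [gaitsim_config()].
#' @param modalities Modalities to generate.
#' @return A list of [recording()]s.
#' @export
simulate_recordings <- function(cfg, modalities = c("emg", "robot")) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  subjects <- sprintf("S%04d", seq_len(cfg$n_subjects))
  recs <- list()
  for (s in subjects)
    for (a in ACTIVITIES)
      for (k in seq_len(cfg$trials_per_activity))
        recs <- c(recs, unname(simulate_trial(s, a, k, cfg, modalities)))
  recs
}

#' Simulate a dataset on disk
#'
#' Writes one CSV per trial and modality plus a JSON manifest in the same
#' layout [read_recording()] consumes, and reports per-activity duration
#' summaries.
#'
#' @param cfg A [gaitsim_config()].
#' @param dir Output directory (created if needed).
#' @param modalities Modalities to generate.
#' @return Invisibly, a list with the manifest data.frame and a
#'   `duration_summary` data.frame (per-activity mean/SD seconds).
#' @export
simulate_dataset <- function(cfg, dir, modalities = c("emg", "robot")) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    abort_("locomode_io_error", "cannot create output directory %s", dir)
  subjects <- sprintf("S%04d", seq_len(cfg$n_subjects))
  rows <- list()
  durs <- list()
  for (s in subjects) {
    for (a in ACTIVITIES) {
      for (k in seq_len(cfg$trials_per_activity)) {
        recs <- simulate_trial(s, a, k, cfg, modalities)
        for (m in names(recs)) {
          f <- sprintf("%s_%s_%d_%s.csv", s, a, k, m)
          write_recording(recs[[m]], file.path(dir, f))
          rows[[length(rows) + 1L]] <- data.frame(
            file = f, subject_id = s, activity = a, trial_index = k,
            modality = m, sampling_rate_hz = recs[[m]]$sampling_rate_hz,
            stringsAsFactors = FALSE)
        }
        durs[[length(durs) + 1L]] <-
          data.frame(activity = a, duration_s = duration(recs[[1]]))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.json"))
  dd <- do.call(rbind, durs)
  summ <- aggregate(duration_s ~ activity, dd,
                    function(x) c(mean = mean(x), sd = sd(x)))
  invisible(list(manifest = manifest, duration_summary = summ))
}
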