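# Shared fixtures, built in code.

# Cheap config for unit tests: same protocol, lower sample rate.
quick_config <- function(...) {
  simulation_config(sample_rate_hz = 64, ...)
}

# Noise- and jitter-free config, so trajectories map deterministically to
# channels and features.
noiseless_config <- function(sample_rate_hz = 64, ...) {
  simulation_config(sample_rate_hz = sample_rate_hz,
                    accel_noise_sd_g = 0, gyro_noise_sd_dps = 0,
                    rom_jitter_frac = 0, catch_depth_jitter_sd = 0, ...)
}

# A recording built from explicit channel matrices.
make_recording <- function(accel, gyro, mas_label = 0, fs = 256,
                           subject_id = "T01") {
  imu_recording(subject_id, mas_label, fs, accel, gyro)
}

# A movement portion of length n with given channel content (default:
# standard-normal accel, gyro), used where only the windowing arithmetic
# matters.
fake_portion <- function(n, mas_label = 0, subject_id = "P01", fs = 256,
                         accel = NULL, gyro = NULL) {
  if (is.null(accel)) accel <- matrix(stats::rnorm(3 * n), n, 3)
  if (is.null(gyro)) gyro <- matrix(stats::rnorm(3 * n), n, 3)
  rec <- make_recording(accel, gyro, mas_label, fs, subject_id)
  movement_portion(rec, 0, n)
}

# A feature matrix of perfectly separable classes: per class a distinct
# feature centroid, per subject `segs` segments with small within-subject
# scatter. Labels and subject counts given as a named vector like
# c(`0` = 4, `3` = 4).
separable_features <- function(class_subjects, segs = 3, n_feat = 5,
                               scatter = 0.01, seed = 42) {
  set.seed(seed)
  rows <- list()
  sid <- 0
  for (lab in names(class_subjects)) {
    centroid <- as.integer(lab) * 10 + seq_len(n_feat)
    for (j in seq_len(class_subjects[[lab]])) {
      sid <- sid + 1
      for (k in seq_len(segs)) {
        vals <- centroid + stats::rnorm(n_feat, 0, scatter)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sprintf("S%02d", sid),
          mas_label = as.integer(lab), scheme = "nonoverlap",
          segment_index = k - 1L,
          t(stats::setNames(vals, paste0("f", seq_len(n_feat)))))
      }
    }
  }
  do.call(rbind, rows)
}

# Independent oracle: extension-phase minimum angular speed of a zero-noise
# trajectory, measured over the central band of the excursion.
min_extension_speed <- function(config, label) {
  ang <- simulate_angle_trajectory(config, label)
  fs <- config$sample_rate_hz
  n_lead <- round(config$baseline_lead_s * fs)
  n_half <- round(config$cycle_period_s / 2 * fs)
  ext <- ang[n_lead + seq_len(n_half)]          # first extension half-cycle
  v <- diff(ext) * fs
  rom <- max(ext) - min(ext)
  band <- ext[-1] > min(ext) + 0.2 * rom & ext[-1] < min(ext) + 0.8 * rom
  min(abs(v[band]))
}
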