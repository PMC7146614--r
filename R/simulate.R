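#' Simulate an elbow-angle trajectory for one passive stretch assessment
#'
#' Generates the joint-angle time series of a passive stretch test: a lead
#' hold at full flexion (angle 0), `n_cycles` flexion-extension cycles and a
#' trailing hold. Each cycle is a raised-cosine excursion from 0 to the
#' grade's range of motion and back. For labels > 0 the extension half-cycle
#' passes through a spastic catch: angular velocity is transiently reduced by
#' a fraction `catch_depth` in a Gaussian-shaped region centred at
#' `catch_angle_frac` of the excursion, implemented as a time warp so the
#' half-cycle still completes in `cycle_period_s / 2` seconds (the examiner
#' pushes through the resistance at constant pace).
#'
#' @param config A [simulation_config()].
#' @param mas_label Integer MAS label code in `0:5`.
#' @param rom_deg,catch_depth Optional subject-specific overrides of the
#'   per-label defaults in `config` (used by [simulate_cohort()] to add
#'   between-subject variability).
#' @return Numeric vector of elbow angles in degrees, of length
#'   `round((baseline_lead_s + n_cycles * cycle_period_s + baseline_trail_s)
#'   * sample_rate_hz)`. Fully deterministic: noise enters only in
#'   [angle_to_imu()].
#' @examples
#' ang <- simulate_angle_trajectory(simulation_config(), mas_label = 1)
#' length(ang)  # 7 s at 256 Hz = 1792 samples
#' @export
simulate_angle_trajectory <- function(config, mas_label,
                                      rom_deg = NULL, catch_depth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(mas_label) != 1 || !mas_label %in% mas_labels()) {
    stop("unknown MAS label: ", mas_label, call. = FALSE)
  }
  i <- mas_label + 1
  rom <- if (is.null(rom_deg)) config$rom_deg[i] else rom_deg
  depth <- if (is.null(catch_depth)) config$catch_depth[i] else catch_depth
  frac <- config$catch_angle_frac[i]
  width <- config$catch_width_frac[i]
  fs <- config$sample_rate_hz

  n_lead <- round(config$baseline_lead_s * fs)
  n_trail <- round(config$baseline_trail_s * fs)
  n_half <- round(config$cycle_period_s / 2 * fs)
  if (n_half < 2) stop("cycle too short for the sample rate", call. = FALSE)

  ext <- half_cycle_angles(rom, depth, frac, width, n_half, extension = TRUE)
  flx <- half_cycle_angles(rom, 0, frac, width, n_half, extension = FALSE)
  cycle <- c(ext, flx)
  c(rep(0, n_lead), rep(cycle, config$n_cycles), rep(0, n_trail))
}

# One half-cycle of the raised-cosine stretch, sampled at n_samp points on
# the half-open time grid [0, T/2). A multiplicative velocity notch of depth
# `depth` (Gaussian in normalized angle, s.d. width/2) is applied through a
# time warp that preserves the half-cycle duration and end points.
half_cycle_angles <- function(rom, depth, frac, width, n_samp, extension) {
  s <- seq(0, 1, length.out = 4097)
  theta <- rom / 2 * (1 - cos(pi * s))           # 0 -> rom
  if (depth > 0 && rom > 0) {
    theta_hat <- theta / rom
    mult <- 1 - depth * exp(-0.5 * ((theta_hat - frac) / (width / 2))^2)
    dt <- c(0, diff(s)) / mult                   # local slow-down
    tt <- cumsum(dt)
    tt <- tt / tt[length(tt)]
  } else {
    tt <- s
  }
  u <- seq(0, 1, length.out = n_samp + 1)[seq_len(n_samp)]
  ang <- stats::approx(tt, theta, xout = u)$y
  if (extension) ang else rom - ang              # flexion runs rom -> 0
}

#' Convert an angle trajectory into IMU channels
#'
#' Forward model of a forearm-mounted sensor rotating with the elbow angle
#' about the sensor x axis. The gyroscope x channel is the first difference
#' of the angle times the sample rate (deg/s); gyro y and z carry noise only.
#' The accelerometer reads the gravity unit vector rotated through the elbow
#' angle: `ay = sin(angle)`, `az = cos(angle)` (in g), so the roll angle
#' recomputed from noiseless acceleration recovers the joint angle; `ax`
#' carries noise only. Gaussian noise with the configured standard deviations
#' is added to every axis, drawn from the current RNG stream.
#'
#' @param angles Nonempty numeric vector of elbow angles in degrees.
#' @param config A [simulation_config()].
#' @return List with numeric matrices `accel` (n x 3, g) and `gyro`
#'   (n x 3, deg/s).
#' @export
angle_to_imu <- function(angles, config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- length(angles)
  if (n < 1) stop("angle trajectory is empty", call. = FALSE)
  fs <- config$sample_rate_hz
  d <- if (n >= 2) diff(angles) else numeric(0)
  gx <- fs * c(if (n >= 2) d[1] else 0, d)
  rad <- angles * pi / 180
  accel <- cbind(ax = numeric(n), ay = sin(rad), az = cos(rad))
  gyro <- cbind(gx = gx, gy = numeric(n), gz = numeric(n))
  if (config$accel_noise_sd_g > 0) {
    accel <- accel + matrix(stats::rnorm(3 * n, 0, config$accel_noise_sd_g), n, 3)
  }
  if (config$gyro_noise_sd_dps > 0) {
    gyro <- gyro + matrix(stats::rnorm(3 * n, 0, config$gyro_noise_sd_dps), n, 3)
  }
  list(accel = accel, gyro = gyro)
}

#' Simulate a single labeled recording
#'
#' Draws subject-specific movement parameters (range of motion and catch
#' depth jittered around the per-label defaults) and sensor noise from the
#' current RNG stream, then assembles an [imu_recording()].
#'
#' @param config A [simulation_config()].
#' @param mas_label Integer MAS label code in `0:5`.
#' @param subject_id Character identifier.
#' @return An [imu_recording()].
#' @export
simulate_recording <- function(config, mas_label, subject_id) {
  i <- mas_label + 1
  rom <- config$rom_deg[i] *
    max(0.5, min(1.5, 1 + stats::rnorm(1, 0, config$rom_jitter_frac)))
  depth <- config$catch_depth[i]
  if (mas_label > 0 && config$catch_depth_jitter_sd > 0) {
    depth <- min(0.97, max(0, depth + stats::rnorm(1, 0, config$catch_depth_jitter_sd)))
  }
  ang <- simulate_angle_trajectory(config, mas_label,
                                   rom_deg = rom, catch_depth = depth)
  ch <- angle_to_imu(ang, config)
  imu_recording(subject_id, mas_label, config$sample_rate_hz,
                ch$accel, ch$gyro)
}

#' Simulate a labeled cohort of passive-stretch recordings
#'
#' One recording per subject, with the number of subjects per MAS label given
#' by `cohort_spec`. The default composition elsewhere in the package is
#' 17/13/7/6/4/1 subjects across labels 0-5 (48 in total). Reproducible:
#' identical `(config, cohort_spec, seed)` give bitwise-identical channels.
#'
#' @param cohort_spec Named vector mapping MAS label (`"0"`..`"5"`) to a
#'   nonnegative subject count. Empty spec gives an empty list.
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return List of [imu_recording()] objects with unique subject ids.
#' @examples
#' cohort <- simulate_cohort(c(`0` = 2, `3` = 1), simulation_config(), seed = 7)
#' length(cohort)
#' @export
simulate_cohort <- function(cohort_spec, config = simulation_config(),
                            seed = config$seed) {
  cohort_spec <- validate_cohort_spec(cohort_spec)
  set.seed(as.integer(seed))
  out <- list()
  k <- 0L
  for (lab_chr in names(cohort_spec)) {
    lab <- as.integer(lab_chr)
    for (j in seq_len(cohort_spec[[lab_chr]])) {
      k <- k + 1L
      id <- sprintf("S%03d_MAS%d", k, lab)
      out[[k]] <- simulate_recording(config, lab, id)
    }
  }
  out
}
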