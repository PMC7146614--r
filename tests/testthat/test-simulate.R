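test_that("trajectory duration follows the protocol arithmetic", {
  cfg <- simulation_config()
  for (lab in c(0, 2, 5)) {
    expect_length(simulate_angle_trajectory(cfg, lab), 1792)  # 7 s at 256 Hz
  }
  cfg64 <- quick_config()
  expect_length(simulate_angle_trajectory(cfg64, 1), 7 * 64)
  cfg_short <- simulation_config(n_cycles = 2, baseline_lead_s = 0.5,
                                 baseline_trail_s = 0)
  expect_length(simulate_angle_trajectory(cfg_short, 0), round(2.5 * 256))
})

test_that("trajectory rejects bad labels and durations", {
  cfg <- simulation_config()
  expect_error(simulate_angle_trajectory(cfg, 6), "unknown MAS label")
  expect_error(simulate_angle_trajectory(cfg, -1), "unknown MAS label")
  expect_error(simulation_config(cycle_period_s = 0), "positive")
  expect_error(simulation_config(baseline_lead_s = -1), "nonnegative")
})

test_that("grade 0 extension is notch-free; graded labels slow at the catch", {
  cfg <- noiseless_config(sample_rate_hz = 256)
  fs <- cfg$sample_rate_hz
  n_lead <- round(cfg$baseline_lead_s * fs)
  n_half <- round(cfg$cycle_period_s / 2 * fs)
  ext_speed <- function(lab) {
    ang <- simulate_angle_trajectory(cfg, lab)
    abs(diff(ang[n_lead + seq_len(n_half)])) * fs
  }
  # label 0: raised cosine, speed is unimodal (rises to one peak, then falls)
  v0 <- ext_speed(0)
  tol <- 1e-6 * max(v0)
  i_max <- which.max(v0)
  expect_true(all(diff(v0[1:i_max]) >= -tol))
  expect_true(all(diff(v0[i_max:length(v0)]) <= tol))
  # label 3: the catch carves an interior local minimum into the profile
  v3 <- ext_speed(3)
  interior <- v3[round(0.2 * length(v3)):round(0.8 * length(v3))]
  expect_lt(min(interior), 0.9 * min(interior[1], interior[length(interior)]))
  # at least half the configured notch depth survives the duration-preserving
  # time warp (which uniformly speeds the rest of the half-cycle up)
  band <- min_extension_speed(cfg, 3)
  base <- min_extension_speed(cfg, 0) * cfg$rom_deg[4] / cfg$rom_deg[1]
  expect_lt(band / base, 1 - cfg$catch_depth[4] / 2)
})

test_that("label 5 is near-rigid: excursion bounded by its tiny ROM", {
  cfg <- simulation_config()
  ang <- simulate_angle_trajectory(cfg, 5)
  expect_lte(diff(range(ang)), cfg$rom_deg[6] + 1e-9)
  expect_lt(diff(range(ang)), 0.1 * cfg$rom_deg[1])
})

test_that("minimum extension-phase speed is non-increasing in MAS label", {
  cfg <- noiseless_config(sample_rate_hz = 256)
  speeds <- vapply(0:5, function(l) min_extension_speed(cfg, l), numeric(1))
  expect_true(all(diff(speeds) <= 0))
})

test_that("angle_to_imu matches its kinematic contract", {
  cfg <- noiseless_config()
  fs <- cfg$sample_rate_hz
  # constant angle -> zero gyro everywhere
  ch <- angle_to_imu(rep(30, 50), cfg)
  expect_true(all(ch$gyro == 0))
  # zero angle -> gravity entirely along z
  ch0 <- angle_to_imu(rep(0, 20), cfg)
  expect_equal(unname(ch0$accel), cbind(rep(0, 20), 0, 1))
  # linear ramp 0..90 deg over 1 s -> designated axis reads 90 deg/s
  ramp <- seq(0, 90, length.out = fs + 1)
  ch_r <- angle_to_imu(ramp, cfg)
  fd_oracle <- diff(ramp) * fs                       # finite differences
  expect_equal(ch_r$gyro[-1, "gx"], fd_oracle, tolerance = 1e-10)
  expect_true(all(abs(ch_r$gyro[, "gx"] - 90) < 1e-9))
  expect_error(angle_to_imu(numeric(0), cfg), "empty")
})

test_that("cohorts honour the spec, have unique ids, and are reproducible", {
  cfg <- quick_config()
  spec <- c(`0` = 3, `2` = 2, `5` = 1)
  cohort <- simulate_cohort(spec, cfg, seed = 11)
  expect_length(cohort, 6)
  labs <- vapply(cohort, function(r) r$mas_label, integer(1))
  expect_equal(as.integer(table(factor(labs, levels = 0:5))),
               c(3L, 0L, 2L, 0L, 0L, 1L))
  ids <- vapply(cohort, function(r) r$subject_id, character(1))
  expect_equal(anyDuplicated(ids), 0L)
  # determinism: bitwise-identical channels under the same seed
  again <- simulate_cohort(spec, cfg, seed = 11)
  expect_identical(lapply(cohort, `[[`, "accel"), lapply(again, `[[`, "accel"))
  expect_identical(lapply(cohort, `[[`, "gyro"), lapply(again, `[[`, "gyro"))
  # a different seed changes the channels
  other <- simulate_cohort(spec, cfg, seed = 12)
  expect_false(identical(cohort[[1]]$accel, other[[1]]$accel))
  expect_length(simulate_cohort(c(), cfg, seed = 1), 0)
})

test_that("noiseless same-grade recordings map to identical features", {
  cfg <- noiseless_config()
  a <- simulate_cohort(c(`0` = 1), cfg, seed = 1)[[1]]
  b <- simulate_cohort(c(`0` = 1), cfg, seed = 99)[[1]]
  seg_a <- segment_nonoverlap(extract_middle_cycles(a))[[1]]
  seg_b <- segment_nonoverlap(extract_middle_cycles(b))[[1]]
  expect_identical(featurize(seg_a, "FS2")$values, featurize(seg_b, "FS2")$values)
})
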