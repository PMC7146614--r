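#' MAS label codes
#'
#' The modified Ashworth scale has six levels, `0, 1, 1+, 2, 3, 4`, coded
#' here as integer labels `0:5` for supervised learning (`1+` is label 2).
#'
#' @return Integer vector `0:5`.
#' @export
mas_labels <- function() 0:5

#' @rdname mas_labels
#' @return `mas_scores()` returns the clinical score names as character.
#' @export
mas_scores <- function() c("0", "1", "1+", "2", "3", "4")

#' Simulation configuration for synthetic passive-stretch recordings
#'
#' Defines the generative model for one passive stretch assessment: a
#' quasi-static hold, `n_cycles` elbow flexion-extension cycles at
#' `1/cycle_period_s` cycles per second, and a trailing hold, sampled at
#' `sample_rate_hz`. Grade-dependent movement is controlled by per-label
#' vectors (index 1 = label 0, ..., index 6 = label 5): the angular excursion
#' `rom_deg` shrinks with severity until near-rigidity at label 5, while the
#' spastic catch -- a transient slow-down during extension -- deepens and (at
#' mid grades) widens with severity via `catch_depth`, `catch_angle_frac` and
#' `catch_width_frac`.
#'
#' @param sample_rate_hz Sampling rate in Hz (default 256).
#' @param n_cycles Number of flexion-extension cycles (default 5).
#' @param cycle_period_s Duration of one cycle in seconds (default 1).
#' @param baseline_lead_s,baseline_trail_s Quasi-static hold durations in
#'   seconds before and after the movement (default 1 each).
#' @param rom_deg Length-6 numeric, full angular excursion in degrees per
#'   label; must be non-increasing, near zero for label 5 (MAS 4, "rigid").
#' @param catch_angle_frac Length-6 numeric in (0, 1), fraction of the
#'   excursion at which the catch is centred.
#' @param catch_depth Length-6 numeric in \[0, 1): fractional velocity drop at
#'   the catch; must be 0 for label 0 and non-decreasing with label.
#' @param catch_width_frac Length-6 numeric, width of the slowed region as a
#'   fraction of the excursion (Gaussian full width at half depth ~ 2.35x).
#' @param rom_jitter_frac Between-subject relative jitter (s.d.) on `rom_deg`.
#' @param catch_depth_jitter_sd Between-subject additive jitter (s.d.) on
#'   `catch_depth` (never applied to label 0).
#' @param accel_noise_sd_g Accelerometer noise s.d. per axis, in g.
#' @param gyro_noise_sd_dps Gyroscope noise s.d. per axis, in deg/s.
#' @param seed Default integer seed used by [simulate_cohort()] when none is
#'   given.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_angle_trajectory()]
#' @examples
#' cfg <- simulation_config()
#' cfg$rom_deg
#' @export
simulation_config <- function(sample_rate_hz = 256,
                              n_cycles = 5,
                              cycle_period_s = 1,
                              baseline_lead_s = 1,
                              baseline_trail_s = 1,
                              rom_deg = c(120, 110, 100, 80, 50, 8),
                              catch_angle_frac = c(0.50, 0.75, 0.55, 0.45, 0.35, 0.50),
                              catch_depth = c(0, 0.35, 0.50, 0.65, 0.80, 0.90),
                              catch_width_frac = c(0.10, 0.08, 0.18, 0.35, 0.50, 0.25),
                              rom_jitter_frac = 0.05,
                              catch_depth_jitter_sd = 0.03,
                              accel_noise_sd_g = 0.01,
                              gyro_noise_sd_dps = 1,
                              seed = 1L) {
  cfg <- list(
    sample_rate_hz = sample_rate_hz, n_cycles = n_cycles,
    cycle_period_s = cycle_period_s,
    baseline_lead_s = baseline_lead_s, baseline_trail_s = baseline_trail_s,
    rom_deg = rom_deg, catch_angle_frac = catch_angle_frac,
    catch_depth = catch_depth, catch_width_frac = catch_width_frac,
    rom_jitter_frac = rom_jitter_frac,
    catch_depth_jitter_sd = catch_depth_jitter_sd,
    accel_noise_sd_g = accel_noise_sd_g,
    gyro_noise_sd_dps = gyro_noise_sd_dps,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  pos <- c("sample_rate_hz", "n_cycles", "cycle_period_s")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop("'", f, "' must be a single positive number", call. = FALSE)
    }
  }
  for (f in c("baseline_lead_s", "baseline_trail_s",
              "accel_noise_sd_g", "gyro_noise_sd_dps",
              "rom_jitter_frac", "catch_depth_jitter_sd")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0) {
      stop("'", f, "' must be a single nonnegative number", call. = FALSE)
    }
  }
  for (f in c("rom_deg", "catch_angle_frac", "catch_depth", "catch_width_frac")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 6) {
      stop("'", f, "' must be a numeric vector of length 6 (one per MAS label)",
           call. = FALSE)
    }
  }
  if (any(diff(cfg$rom_deg) > 0)) {
    stop("'rom_deg' must be non-increasing across MAS labels", call. = FALSE)
  }
  if (cfg$catch_depth[1] != 0) {
    stop("'catch_depth' must be 0 for MAS label 0 (no increase in tone)",
         call. = FALSE)
  }
  if (any(diff(cfg$catch_depth) < 0)) {
    stop("'catch_depth' must be non-decreasing across MAS labels", call. = FALSE)
  }
  if (any(cfg$catch_depth < 0 | cfg$catch_depth >= 1)) {
    stop("'catch_depth' values must lie in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  %g Hz, %d cycle(s) of %g s, holds %g + %g s\n",
              x$sample_rate_hz, x$n_cycles, x$cycle_period_s,
              x$baseline_lead_s, x$baseline_trail_s))
  cat("  label      :", paste(format(mas_scores(), width = 6), collapse = ""), "\n")
  cat("  rom_deg    :", paste(format(x$rom_deg, width = 6), collapse = ""), "\n")
  cat("  catch_depth:", paste(format(x$catch_depth, width = 6), collapse = ""), "\n")
  cat(sprintf("  noise: accel %g g, gyro %g deg/s\n",
              x$accel_noise_sd_g, x$gyro_noise_sd_dps))
  invisible(x)
}

#' The well-separated validation regime
#'
#' A [simulation_config()] in which the six grades are clearly
#' distinguishable: low sensor noise, catch depths spaced by about 0.2 with
#' widths growing with severity, and tight between-subject jitter. Used to
#' validate that the pipeline recovers the generating grade when the signal
#' supports it; the [simulation_config()] defaults keep the harder,
#' clinically more realistic narrow low-grade catches.
#'
#' @param accel_noise_sd_g,gyro_noise_sd_dps Noise scales, default 0.01 g
#'   and 1 deg/s.
#' @param ... Further overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
easy_regime_config <- function(accel_noise_sd_g = 0.01,
                               gyro_noise_sd_dps = 1, ...) {
  simulation_config(
    catch_depth = c(0, 0.35, 0.55, 0.75, 0.88, 0.95),
    catch_width_frac = c(0.10, 0.20, 0.30, 0.40, 0.50, 0.30),
    rom_jitter_frac = 0.02,
    catch_depth_jitter_sd = 0.01,
    accel_noise_sd_g = accel_noise_sd_g,
    gyro_noise_sd_dps = gyro_noise_sd_dps,
    ...
  )
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the simulation model, the
#' cohort composition, preprocessing thresholds, the segmentation schemes and
#' feature sets to run, the classifier list, the cross-validation granularity
#' and a root seed.
#'
#' @param simulation A [simulation_config()].
#' @param cohort Named integer vector mapping MAS label (`"0"`..`"5"`) to the
#'   number of subjects. The default reproduces a 48-subject clinical cohort
#'   with 17/13/7/6/4/1 subjects across the six grades.
#' @param gyro_threshold_dps Angular-speed threshold (deg/s) separating
#'   quasi-static baseline from movement; see [trim_baseline()].
#' @param min_active_s Minimum contiguous supra-threshold duration (s).
#' @param schemes Segmentation schemes to run (subset of
#'   `c("nonoverlap", "overlap50")`).
#' @param feature_sets Feature sets to run (subset of `c("FS1", "FS2")`).
#' @param classifiers Classifier names (subset of
#'   `c("DT", "RF", "SVM", "LDA", "MLP")`); must be nonempty.
#' @param granularity Leave-one-out unit: `"subject"` (leave-one-subject-out,
#'   the default) or `"segment"`.
#' @param seed Root integer seed for the whole run.
#' @param control A [classifier_control()].
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            cohort = c(`0` = 17, `1` = 13, `2` = 7,
                                       `3` = 6, `4` = 4, `5` = 1),
                            gyro_threshold_dps = 10,
                            min_active_s = 0.25,
                            schemes = c("nonoverlap", "overlap50"),
                            feature_sets = c("FS1", "FS2"),
                            classifiers = c("DT", "RF", "SVM", "LDA", "MLP"),
                            granularity = c("subject", "segment"),
                            seed = 1L,
                            control = classifier_control()) {
  granularity <- match.arg(granularity)
  schemes <- match.arg(schemes, c("nonoverlap", "overlap50"), several.ok = TRUE)
  feature_sets <- match.arg(feature_sets, c("FS1", "FS2"), several.ok = TRUE)
  if (length(classifiers) == 0) {
    stop("'classifiers' must name at least one classifier", call. = FALSE)
  }
  classifiers <- match.arg(classifiers, c("DT", "RF", "SVM", "LDA", "MLP"),
                           several.ok = TRUE)
  if (!inherits(simulation, "simulation_config")) {
    stop("'simulation' must be a simulation_config object", call. = FALSE)
  }
  cohort <- validate_cohort_spec(cohort)
  if (!is.numeric(gyro_threshold_dps) || gyro_threshold_dps <= 0) {
    stop("'gyro_threshold_dps' must be positive", call. = FALSE)
  }
  if (!is.numeric(min_active_s) || min_active_s <= 0) {
    stop("'min_active_s' must be positive", call. = FALSE)
  }
  structure(list(simulation = simulation, cohort = cohort,
                 gyro_threshold_dps = gyro_threshold_dps,
                 min_active_s = min_active_s,
                 schemes = schemes, feature_sets = feature_sets,
                 classifiers = classifiers, granularity = granularity,
                 seed = as.integer(seed), control = control),
            class = "pipeline_config")
}

validate_cohort_spec <- function(cohort) {
  if (length(cohort) == 0) return(stats::setNames(integer(0), character(0)))
  if (is.null(names(cohort)) || any(!names(cohort) %in% as.character(0:5))) {
    stop("cohort must be named by MAS labels \"0\"..\"5\"", call. = FALSE)
  }
  if (any(cohort < 0) || any(cohort != round(cohort))) {
    stop("cohort counts must be nonnegative integers", call. = FALSE)
  }
  stats::setNames(as.integer(cohort), names(cohort))
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirror the arguments of [simulation_config()] and
#' [pipeline_config()]; per-label vectors are YAML sequences, the cohort a
#' mapping from label to count. Keys not present keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_keys <- names(formals(simulation_config))
  sim <- do.call(simulation_config, raw[intersect(names(raw), sim_keys)])
  # `seed` seeds both the simulation default and the pipeline root
  top <- raw[setdiff(names(raw), setdiff(sim_keys, "seed"))]
  if (!is.null(top$cohort)) top$cohort <- unlist(top$cohort)
  do.call(pipeline_config, c(list(simulation = sim), top))
}
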