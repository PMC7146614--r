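#' Locate the movement interval of a recording by angular velocity
#'
#' The quasi-static baseline holds before and after the stretch manoeuvre are
#' identified from the gyroscope vector magnitude and discarded: the function
#' returns the smallest 0-based half-open sample interval containing every
#' run of samples whose gyro magnitude stays at or above
#' `gyro_threshold_dps` for at least `min_active_s` contiguous seconds.
#' Shorter supra-threshold bursts (sensor noise, small adjustments) do not
#' extend the interval.
#'
#' @param recording An [imu_recording()].
#' @param gyro_threshold_dps Positive threshold in deg/s (default 10, an
#'   order of magnitude below the peak speed of a 1 Hz stretch cycle).
#' @param min_active_s Positive debounce duration in seconds (default 0.25).
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @examples
#' rec <- simulate_cohort(c(`1` = 1), simulation_config(), seed = 1)[[1]]
#' trim_baseline(rec)
#' @export
trim_baseline <- function(recording, gyro_threshold_dps = 10,
                          min_active_s = 0.25) {
  stopifnot(inherits(recording, "imu_recording"))
  if (gyro_threshold_dps <= 0) stop("'gyro_threshold_dps' must be positive", call. = FALSE)
  if (min_active_s <= 0) stop("'min_active_s' must be positive", call. = FALSE)
  mag <- sqrt(rowSums(recording$gyro^2))
  active <- mag >= gyro_threshold_dps
  min_run <- max(1L, ceiling(min_active_s * recording$sample_rate_hz))
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) {
    stop("no movement detected: no gyro-magnitude run of >= ", min_active_s,
         " s stays above ", gyro_threshold_dps, " deg/s", call. = FALSE)
  }
  c(start = starts[which(keep)[1]] - 1L,
    end = ends[utils::tail(which(keep), 1)])
}

#' Extract the middle three flexion-extension cycles
#'
#' Divides the active interval of a recording into five equal-length
#' contiguous subsets and keeps the middle three, discarding the first and
#' last (the least stable cycles). With an interval of length `L` the subsets
#' have `floor(L / 5)` samples (remainder samples fall in the trailing part
#' and are dropped), so the portion has exactly `3 * floor(L / 5)` samples.
#'
#' @param recording An [imu_recording()].
#' @param active_interval 0-based half-open `c(start, end)` as returned by
#'   [trim_baseline()]; defaults to trimming with default thresholds.
#' @return A [movement_portion()].
#' @export
extract_middle_cycles <- function(recording,
                                  active_interval = trim_baseline(recording)) {
  start <- active_interval[[1]]
  end <- active_interval[[2]]
  L <- end - start
  if (L < 5) {
    stop("active interval has ", L, " samples; need at least 5 to divide ",
         "into five subsets", call. = FALSE)
  }
  b <- L %/% 5L
  movement_portion(recording, start + b, start + 4L * b)
}
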