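#' Construct an IMU recording
#'
#' One subject's labeled six-channel inertial time series: triaxial
#' acceleration in g and triaxial angular velocity in deg/s, sampled at
#' `sample_rate_hz`, with the MAS label as an integer code 0-5.
#'
#' @param subject_id Character scalar identifier.
#' @param mas_label Integer MAS label code in `0:5` (`1+` is 2).
#' @param sample_rate_hz Positive sampling rate in Hz.
#' @param accel Numeric n x 3 matrix, columns `ax, ay, az`, in g.
#' @param gyro Numeric n x 3 matrix, columns `gx, gy, gz`, in deg/s; must
#'   have the same number of rows as `accel`.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(subject_id, mas_label, sample_rate_hz, accel, gyro) {
  accel <- as_channel_matrix(accel, c("ax", "ay", "az"))
  gyro <- as_channel_matrix(gyro, c("gx", "gy", "gz"))
  if (nrow(accel) != nrow(gyro)) {
    stop("accel and gyro must have the same number of samples", call. = FALSE)
  }
  if (nrow(accel) < 1) stop("recording must contain at least one sample", call. = FALSE)
  if (!mas_label %in% mas_labels()) {
    stop("mas_label must be an integer in 0..5, got: ", mas_label, call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be positive", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id),
                 mas_label = as.integer(mas_label),
                 sample_rate_hz = sample_rate_hz,
                 accel = accel, gyro = gyro),
            class = "imu_recording")
}

as_channel_matrix <- function(x, cols) {
  x <- as.matrix(x)
  if (ncol(x) != 3 || !is.numeric(x)) {
    stop("expected a numeric n x 3 matrix", call. = FALSE)
  }
  colnames(x) <- cols
  x
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject %s, MAS label %d (score %s)\n",
              x$subject_id, x$mas_label, mas_scores()[x$mas_label + 1]))
  cat(sprintf("  %d samples at %g Hz (%.2f s)\n", nrow(x$accel),
              x$sample_rate_hz, nrow(x$accel) / x$sample_rate_hz))
  invisible(x)
}

#' Construct a movement portion
#'
#' The sub-series of a recording covering the middle three flexion-extension
#' cycles, as produced by [extract_middle_cycles()]. `source_bounds` records
#' the 0-based half-open sample interval into the parent recording.
#'
#' @param recording Parent [imu_recording()].
#' @param start,end 0-based half-open bounds into the parent.
#' @return An object of class `movement_portion` (also an `imu_recording`).
#' @export
movement_portion <- function(recording, start, end) {
  n <- nrow(recording$accel)
  if (start < 0 || end > n || end - start < 3) {
    stop("portion bounds [", start, ", ", end, ") invalid for a recording of ",
         n, " samples (need length >= 3)", call. = FALSE)
  }
  idx <- (start + 1):end
  structure(list(subject_id = recording$subject_id,
                 mas_label = recording$mas_label,
                 sample_rate_hz = recording$sample_rate_hz,
                 accel = recording$accel[idx, , drop = FALSE],
                 gyro = recording$gyro[idx, , drop = FALSE],
                 source_bounds = c(start = start, end = end)),
            class = c("movement_portion", "imu_recording"))
}

#' @export
print.movement_portion <- function(x, ...) {
  cat(sprintf("<movement_portion> subject %s, MAS label %d, %d samples, source [%d, %d)\n",
              x$subject_id, x$mas_label, nrow(x$accel),
              x$source_bounds[["start"]], x$source_bounds[["end"]]))
  invisible(x)
}

#' Construct a segment
#'
#' One fixed-length window of a movement portion, tagged with the windowing
#' scheme and its 0-based window ordinal.
#'
#' @param portion Parent [movement_portion()] (or recording).
#' @param scheme `"nonoverlap"` or `"overlap50"`.
#' @param index 0-based window ordinal (`0:2` for nonoverlap, `0:4` for
#'   overlap50).
#' @param start,end 0-based half-open bounds into the portion.
#' @return An object of class `imu_segment`.
#' @export
imu_segment <- function(portion, scheme, index, start, end) {
  scheme <- match.arg(scheme, c("nonoverlap", "overlap50"))
  max_index <- if (scheme == "nonoverlap") 2L else 4L
  if (index < 0 || index > max_index) {
    stop("index ", index, " out of range for scheme ", scheme, call. = FALSE)
  }
  if (end - start < 1) stop("segment window must be nonempty", call. = FALSE)
  idx <- (start + 1):end
  structure(list(subject_id = portion$subject_id,
                 mas_label = portion$mas_label,
                 sample_rate_hz = portion$sample_rate_hz,
                 scheme = scheme, index = as.integer(index),
                 accel = portion$accel[idx, , drop = FALSE],
                 gyro = portion$gyro[idx, , drop = FALSE]),
            class = "imu_segment")
}

#' @export
print.imu_segment <- function(x, ...) {
  cat(sprintf("<imu_segment> subject %s, MAS label %d, %s window %d, %d samples\n",
              x$subject_id, x$mas_label, x$scheme, x$index, nrow(x$accel)))
  invisible(x)
}
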