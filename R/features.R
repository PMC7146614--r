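#' The seven per-channel statistical features
#'
#' Computes, for one signal channel, the seven statistics used throughout
#' the feature sets: root mean square, mean, (population) standard
#' deviation, energy, spectral energy, absolute difference and (population)
#' variance. Energy is the mean square `sum(x^2)/n`; spectral energy is the
#' Parseval-normalized DFT energy `sum(|X_k|^2)/n^2`, which equals the
#' time-domain energy up to floating point and is retained as a numerical
#' cross-check feature; absolute difference is the mean absolute successive
#' difference `mean(|x[i+1] - x[i]|)`, a standard roughness feature in
#' activity recognition.
#'
#' @param x Numeric vector of length at least 2.
#' @return Named numeric vector of length 7, names `rms, mean, std, energy,
#'   spectral_energy, abs_diff, variance`.
#' @examples
#' channel_stats(c(1, -1, 1, -1))
#' @export
channel_stats <- function(x) {
  n <- length(x)
  if (n < 2) stop("channel_stats needs at least 2 samples", call. = FALSE)
  if (!is.numeric(x)) stop("channel_stats needs a numeric vector", call. = FALSE)
  m <- sum(x) / n
  v <- sum((x - m)^2) / n
  en <- sum(x^2) / n
  sp <- sum(Mod(stats::fft(x))^2) / n^2
  c(rms = sqrt(en), mean = m, std = sqrt(v), energy = en,
    spectral_energy = sp, abs_diff = sum(abs(diff(x))) / (n - 1), variance = v)
}

#' Roll and pitch from raw acceleration
#'
#' Tilt angles of the sensor estimated from the direction of gravity in the
#' raw accelerometer reading, in degrees:
#' `roll = (180/pi) * atan2(y, z)` and `pitch = (180/pi) * atan2(x, z)`,
#' where `x, y, z` are the axis accelerations in g. Quadrant-aware, range
#' `(-180, 180]`. During slow passive stretch gravity dominates, so no
#' gravity-separation filter is applied. The degenerate input where both
#' arguments are zero returns 0 with a warning.
#'
#' @param y,z,x Numeric vectors (recycled pairwise) of axis accelerations
#'   in g.
#' @return Numeric vector of angles in degrees.
#' @examples
#' roll(0, 1)   # gravity along y: 90 degrees
#' pitch(1, 1)  # 45 degrees
#' @export
roll <- function(y, z) tilt_deg(y, z)

#' @rdname roll
#' @export
pitch <- function(x, z) tilt_deg(x, z)

tilt_deg <- function(a, b) {
  bad <- a == 0 & b == 0
  if (any(bad)) {
    warning("degenerate (0, 0) acceleration; returning 0 degrees", call. = FALSE)
  }
  out <- 180 / pi * atan2(a, b)
  out[bad] <- 0
  out
}

#' Signal magnitude area and signal vector magnitude
#'
#' Two activity-recognition summaries of a pair of acceleration axes.
#' `sma(x, y) = mean(|x| + |y|)` indicates periods of activity versus rest;
#' `sv(x, y) = mean(sqrt(x^2 + y^2))` reflects movement intensity. Both are
#' nonnegative and `sv <= sma` always (triangle inequality).
#'
#' @param x,y Equal-length nonempty numeric vectors.
#' @return Nonnegative scalar.
#' @examples
#' sma(c(1, -1), c(2, -2))  # 3
#' sv(3, 4)                 # 5
#' @export
sma <- function(x, y) {
  check_axis_pair(x, y)
  sum(abs(x) + abs(y)) / length(x)
}

#' @rdname sma
#' @export
sv <- function(x, y) {
  check_axis_pair(x, y)
  sum(sqrt(x^2 + y^2)) / length(x)
}

check_axis_pair <- function(x, y) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  invisible(NULL)
}

stat_names <- c("rms", "mean", "std", "energy", "spectral_energy",
                "abs_diff", "variance")

#' Feature names of a feature set, in canonical order
#'
#' FS1 is the seven statistics on each of the six raw channels
#' (channel-major order `ax, ay, az, gx, gy, gz`), 42 features. FS2 appends
#' the same statistics on the per-sample roll and pitch series (14) plus
#' `sma` and `sv` over the accelerometer x and y axes (2), 58 features.
#'
#' @param feature_set `"FS1"` or `"FS2"`.
#' @return Character vector of 42 or 58 unique names, e.g. `"ax_rms"`,
#'   `"roll_variance"`, `"sma"`.
#' @export
feature_names <- function(feature_set = c("FS1", "FS2")) {
  feature_set <- match.arg(feature_set)
  chans <- c("ax", "ay", "az", "gx", "gy", "gz")
  if (feature_set == "FS2") chans <- c(chans, "roll", "pitch")
  nm <- as.vector(t(outer(chans, stat_names, paste, sep = "_")))
  if (feature_set == "FS2") nm <- c(nm, "sma", "sv")
  nm
}

#' Compute a feature vector from one segment
#'
#' @param segment An [imu_segment()] (any object with `accel`/`gyro`
#'   matrices, `subject_id`, `mas_label`).
#' @param feature_set `"FS1"` (42 features: 7 statistics x 6 raw channels)
#'   or `"FS2"` (58: FS1 plus 7 statistics on each of roll and pitch, plus
#'   `sma` and `sv` of the accelerometer x/y axes).
#' @return An object of class `feature_vector`: list with `subject_id`,
#'   `mas_label`, `scheme`, `feature_set`, and `values`, a named numeric
#'   vector ordered as [feature_names()].
#' @export
featurize <- function(segment, feature_set = c("FS1", "FS2")) {
  feature_set <- match.arg(feature_set)
  chans <- cbind(segment$accel, segment$gyro)
  series <- lapply(seq_len(ncol(chans)), function(j) chans[, j])
  names(series) <- c("ax", "ay", "az", "gx", "gy", "gz")
  if (feature_set == "FS2") {
    series$roll <- roll(chans[, "ay"], chans[, "az"])
    series$pitch <- pitch(chans[, "ax"], chans[, "az"])
  }
  vals <- unlist(lapply(names(series), function(ch) {
    stats::setNames(channel_stats(series[[ch]]),
                    paste(ch, stat_names, sep = "_"))
  }))
  if (feature_set == "FS2") {
    vals <- c(vals, sma = sma(chans[, "ax"], chans[, "ay"]),
              sv = sv(chans[, "ax"], chans[, "ay"]))
  }
  structure(list(subject_id = segment$subject_id,
                 mas_label = segment$mas_label,
                 scheme = segment$scheme %||% NA_character_,
                 feature_set = feature_set,
                 values = vals),
            class = "feature_vector")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s, %d features, subject %s, MAS label %d\n",
              x$feature_set, length(x$values), x$subject_id, x$mas_label))
  invisible(x)
}

#' Build a feature matrix from a list of segments
#'
#' One row per segment: metadata columns `subject_id`, `mas_label`,
#' `scheme`, `segment_index`, followed by the feature columns in the order
#' of [feature_names()].
#'
#' @param segments List of [imu_segment()] objects.
#' @param feature_set `"FS1"` or `"FS2"`.
#' @return A data.frame.
#' @export
feature_matrix <- function(segments, feature_set = c("FS1", "FS2")) {
  feature_set <- match.arg(feature_set)
  nm <- feature_names(feature_set)
  meta <- data.frame(
    subject_id = vapply(segments, function(s) s$subject_id, character(1)),
    mas_label = vapply(segments, function(s) s$mas_label, integer(1)),
    scheme = vapply(segments, function(s) s$scheme %||% NA_character_, character(1)),
    segment_index = vapply(segments, function(s) s$index %||% NA_integer_, integer(1)),
    stringsAsFactors = FALSE
  )
  vals <- t(vapply(segments, function(s) featurize(s, feature_set)$values,
                   numeric(length(nm))))
  colnames(vals) <- nm
  cbind(meta, as.data.frame(vals))
}

#' Metadata column names of a feature matrix
#' @return Character vector of the non-feature columns.
#' @export
feature_meta_cols <- function() c("subject_id", "mas_label", "scheme", "segment_index")
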