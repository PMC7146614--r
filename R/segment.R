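#' Window a movement portion without overlap
#'
#' Splits the three-cycle portion into three non-overlapping windows of
#' `floor(L / 3)` samples at offsets `0, w, 2w`; any trailing remainder is
#' discarded, never padded.
#'
#' @param portion A [movement_portion()] (any `imu_recording` works).
#' @return List of exactly 3 [imu_segment()] objects (`scheme =
#'   "nonoverlap"`, indices 0:2).
#' @export
segment_nonoverlap <- function(portion) {
  L <- nrow(portion$accel)
  if (L < 3) stop("portion of ", L, " samples is too short to segment", call. = FALSE)
  w <- L %/% 3L
  lapply(0:2, function(i) {
    imu_segment(portion, "nonoverlap", i, i * w, (i + 1L) * w)
  })
}

#' Window a movement portion with 50% overlap
#'
#' Windows of `w = floor(L / 3)` samples with hop `h = floor(w / 2)` at
#' offsets `0, h, 2h, 3h, 4h`: each interior window takes half its samples
#' from the previous window's span and half from the next, giving five
#' windows per portion. Consecutive windows share `w - h` samples.
#'
#' @param portion A [movement_portion()].
#' @return List of exactly 5 [imu_segment()] objects (`scheme =
#'   "overlap50"`, indices 0:4).
#' @export
segment_overlap50 <- function(portion) {
  L <- nrow(portion$accel)
  if (L < 3) stop("portion of ", L, " samples is too short to segment", call. = FALSE)
  w <- L %/% 3L
  h <- w %/% 2L
  if (h < 1 || 4L * h + w > L) {
    stop("portion of ", L, " samples is too short for five 50%-overlapping ",
         "windows", call. = FALSE)
  }
  lapply(0:4, function(i) {
    imu_segment(portion, "overlap50", i, i * h, i * h + w)
  })
}

#' Segment a list of portions under one scheme
#'
#' Applies [segment_nonoverlap()] or [segment_overlap50()] to every portion
#' and concatenates the results, preserving subject ids. Per label the
#' segment count is 3 (nonoverlap) or 5 (overlap50) times the number of
#' subjects carrying that label.
#'
#' @param portions List of [movement_portion()] objects.
#' @param scheme `"nonoverlap"` (dataset DS1) or `"overlap50"` (DS2).
#' @return Flat list of [imu_segment()] objects; empty input gives an empty
#'   list.
#' @seealso [segment_counts()]
#' @export
build_segment_table <- function(portions, scheme = c("nonoverlap", "overlap50")) {
  scheme <- match.arg(scheme)
  f <- if (scheme == "nonoverlap") segment_nonoverlap else segment_overlap50
  if (length(portions) == 0) return(list())
  do.call(c, lapply(portions, f))
}

#' Count segments per MAS label
#'
#' @param segments List of [imu_segment()] objects.
#' @return Named integer vector of counts over labels `"0"`..`"5"`.
#' @export
segment_counts <- function(segments) {
  labs <- vapply(segments, function(s) s$mas_label, integer(1))
  tab <- table(factor(labs, levels = mas_labels()))
  stats::setNames(as.integer(tab), names(tab))
}
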