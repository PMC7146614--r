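recording_cols <- c("t_s", "ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps")

#' Write and read recordings as plain CSV
#'
#' The on-disk dialect is one row per sample with columns
#' `t_s, ax_g, ay_g, az_g, gx_dps, gy_dps, gz_dps`. Subject id, MAS label
#' and sample rate live in the cohort manifest (see [write_cohort_csv()]),
#' or can be passed explicitly to the reader.
#'
#' @param recording An [imu_recording()].
#' @param path Output/input CSV path.
#' @return `write_recording_csv()` returns `path` invisibly;
#'   `read_recording_csv()` returns an [imu_recording()].
#' @export
write_recording_csv <- function(recording, path) {
  n <- nrow(recording$accel)
  df <- data.frame((seq_len(n) - 1) / recording$sample_rate_hz,
                   recording$accel, recording$gyro)
  names(df) <- recording_cols
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param subject_id,mas_label Metadata for the recording being read.
#' @param sample_rate_hz Sampling rate; if `NULL`, inferred from the median
#'   spacing of the `t_s` column.
#' @export
read_recording_csv <- function(path, subject_id = "unknown", mas_label = 0,
                               sample_rate_hz = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty recording file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (nrow(df) == 0) stop("empty recording file: ", path, call. = FALSE)
  missing <- setdiff(recording_cols, names(df))
  if (length(missing) > 0) {
    stop("recording file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in recording_cols) {
    if (!is.numeric(df[[col]])) {
      bad_rows <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
      stop("non-numeric values in column '", col, "' of ", path,
           " at data row(s): ", paste(utils::head(bad_rows, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(sample_rate_hz)) {
    dt <- stats::median(diff(df$t_s))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer sample rate from t_s", call. = FALSE)
    sample_rate_hz <- 1 / dt
  }
  imu_recording(subject_id, mas_label, sample_rate_hz,
                as.matrix(df[c("ax_g", "ay_g", "az_g")]),
                as.matrix(df[c("gx_dps", "gy_dps", "gz_dps")]))
}

#' Write and read a cohort with its manifest
#'
#' Writes one CSV per recording plus a `manifest.csv` with columns
#' `subject_id, mas_label, file, sample_rate_hz`; the reader reconstructs
#' the cohort from the manifest.
#'
#' @param recordings List of [imu_recording()] objects.
#' @param dir Output directory (created if needed).
#' @return `write_cohort_csv()` returns the manifest path invisibly;
#'   `read_cohort_csv()` returns a list of [imu_recording()] objects.
#' @export
write_cohort_csv <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(recordings, function(rec) {
    file <- paste0(rec$subject_id, ".csv")
    write_recording_csv(rec, file.path(dir, file))
    data.frame(subject_id = rec$subject_id, mas_label = rec$mas_label,
               file = file, sample_rate_hz = rec$sample_rate_hz,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param manifest_path Path to a `manifest.csv`.
#' @export
read_cohort_csv <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "mas_label", "file", "sample_rate_hz")
  missing <- setdiff(need, names(man))
  if (length(missing) > 0) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    read_recording_csv(file.path(dir, man$file[i]),
                       subject_id = man$subject_id[i],
                       mas_label = man$mas_label[i],
                       sample_rate_hz = man$sample_rate_hz[i])
  })
}

#' Write a feature matrix to CSV
#'
#' Header row = metadata columns then feature names in canonical order
#' ([feature_names()]); one row per segment.
#'
#' @param features data.frame from [feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Run the whole pipeline from a configuration
#'
#' Simulate (or ingest) a cohort, preprocess, segment under the configured
#' schemes, featurize under the configured feature sets, evaluate the
#' classifier grid, and return one report bundle. Fully deterministic under
#' a fixed config seed. If `out_dir` is given, the report (JSON), the long
#' accuracy table, the feature matrices and the per-condition confusion
#' matrices are written there.
#'
#' @param config A [pipeline_config()].
#' @param recordings Optional list of [imu_recording()] objects to analyse
#'   instead of simulating; the config cohort is then ignored.
#' @param out_dir Optional output directory.
#' @return List of class `pipeline_report` with elements `config`, `n_recordings`,
#'   `segment_counts`, `grid` (the [run_condition_grid()] result) and
#'   `report` (plain-list summary also serialized to JSON).
#' @export
run_pipeline <- function(config = pipeline_config(), recordings = NULL,
                         out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    stop("'config' must be a pipeline_config object", call. = FALSE)
  }
  if (is.null(recordings)) {
    recordings <- simulate_cohort(config$cohort, config$simulation,
                                  seed = config$seed)
  }
  if (length(recordings) == 0) stop("no recordings to analyse", call. = FALSE)
  grid <- run_condition_grid(
    recordings,
    classifiers = config$classifiers,
    feature_sets = config$feature_sets,
    schemes = config$schemes,
    granularity = config$granularity,
    seed = config$seed,
    control = config$control,
    gyro_threshold_dps = config$gyro_threshold_dps,
    min_active_s = config$min_active_s
  )
  report <- list(
    n_recordings = length(recordings),
    segment_counts = lapply(grid$segment_counts, as.list),
    segment_totals = lapply(grid$segment_counts, sum),
    accuracy_table = grid$table,
    aggregates = grid$aggregates,
    comparisons = lapply(grid$comparisons, function(cmp) {
      r <- cmp$report
      list(w = r$statistic_w, z = r$z, p_value = r$p_value,
           method = r$method, n_effective = r$n_effective,
           significant = r$significant)
    })
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(grid$table, file.path(out_dir, "accuracies.csv"),
                     row.names = FALSE)
    for (key in names(grid$results)) {
      utils::write.csv(grid$results[[key]]$confusion,
                       file.path(out_dir, paste0("confusion_", key, ".csv")))
    }
  }
  structure(list(config = config, n_recordings = length(recordings),
                 segment_counts = grid$segment_counts, grid = grid,
                 report = report),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d recordings\n", x$n_recordings))
  for (ds in names(x$segment_counts)) {
    cat(sprintf("  %s: %d segments (%s)\n", ds, sum(x$segment_counts[[ds]]),
                paste(x$segment_counts[[ds]], collapse = "/")))
  }
  print(x$grid)
  invisible(x)
}
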