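#' Run the full dataset x feature-set x classifier evaluation grid
#'
#' Preprocesses every recording (baseline trim, middle-cycle extraction),
#' builds the two segment datasets (DS1 = nonoverlapping, DS2 = 50%
#' overlapping windows), computes both feature sets (FS1, FS2), and runs
#' [loocv()] for every combination of dataset, feature set and classifier
#' (2 x 2 x 5 = 20 conditions by default). Aggregates mirror the standard
#' reporting layout for this comparison methodology: median accuracy per
#' (dataset, feature set) cell across classifiers; per feature set pooled
#' over datasets and classifiers; per dataset pooled over feature sets and
#' classifiers; per classifier pooled over all four dataset/feature-set
#' conditions. Paired Wilcoxon signed-rank tests compare FS1 vs FS2 (paired
#' over dataset x classifier) and DS1 vs DS2 (paired over feature set x
#' classifier), on raw two-sided p-values with no multiplicity correction.
#'
#' @param recordings List of [imu_recording()] objects (e.g. from
#'   [simulate_cohort()]).
#' @param classifiers Subset of [classifier_names()].
#' @param feature_sets Subset of `c("FS1", "FS2")`.
#' @param schemes Subset of `c("nonoverlap", "overlap50")`.
#' @param granularity Leave-one-out unit, `"subject"` or `"segment"`.
#' @param seed Integer root seed; each condition derives its own fold seeds.
#' @param control A [classifier_control()].
#' @param gyro_threshold_dps,min_active_s Passed to [trim_baseline()].
#' @return An object of class `condition_grid`: list with `results` (named
#'   list of `cv_result`s, names like `"DS2.FS2.RF"`), `table` (data.frame
#'   of dataset, feature_set, classifier, accuracy), `segment_counts`
#'   (per-label counts per dataset), `aggregates` (the median tables) and
#'   `comparisons` (the two `wilcoxon_report`s with their paired
#'   accuracies).
#' @export
run_condition_grid <- function(recordings,
                               classifiers = classifier_names(),
                               feature_sets = c("FS1", "FS2"),
                               schemes = c("nonoverlap", "overlap50"),
                               granularity = c("subject", "segment"),
                               seed = 1L,
                               control = classifier_control(),
                               gyro_threshold_dps = 10,
                               min_active_s = 0.25) {
  granularity <- match.arg(granularity)
  classifiers <- match.arg(classifiers, classifier_names(), several.ok = TRUE)
  feature_sets <- match.arg(feature_sets, c("FS1", "FS2"), several.ok = TRUE)
  schemes <- match.arg(schemes, c("nonoverlap", "overlap50"), several.ok = TRUE)

  portions <- lapply(recordings, function(r) {
    extract_middle_cycles(r, trim_baseline(r, gyro_threshold_dps, min_active_s))
  })
  ds_name <- c(nonoverlap = "DS1", overlap50 = "DS2")
  segments <- lapply(schemes, build_segment_table, portions = portions)
  names(segments) <- ds_name[schemes]
  seg_counts <- lapply(segments, segment_counts)

  feats <- list()
  for (ds in names(segments)) {
    for (fs in feature_sets) {
      feats[[paste(ds, fs, sep = ".")]] <- feature_matrix(segments[[ds]], fs)
    }
  }

  results <- list()
  rows <- list()
  cond_i <- 0L
  for (ds in names(segments)) {
    for (fs in feature_sets) {
      for (clf in classifiers) {
        cond_i <- cond_i + 1L
        key <- paste(ds, fs, clf, sep = ".")
        results[[key]] <- loocv(feats[[paste(ds, fs, sep = ".")]],
                                classifier = clf, granularity = granularity,
                                seed = as.integer(seed) + 1000L * cond_i,
                                control = control,
                                condition = list(dataset = ds, feature_set = fs))
        rows[[key]] <- data.frame(dataset = ds, feature_set = fs,
                                  classifier = clf,
                                  accuracy = results[[key]]$accuracy,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  med_by <- function(var) {
    vals <- tapply(tab$accuracy, tab[[var]], stats::median)
    data.frame(level = names(vals), median_accuracy = as.numeric(vals),
               stringsAsFactors = FALSE)
  }
  cell <- stats::aggregate(accuracy ~ dataset + feature_set, data = tab,
                           FUN = stats::median)
  names(cell)[names(cell) == "accuracy"] <- "median_accuracy"
  aggregates <- list(cell_medians = cell,
                     by_feature_set = med_by("feature_set"),
                     by_dataset = med_by("dataset"),
                     by_classifier = med_by("classifier"))

  comparisons <- list()
  if (all(c("FS1", "FS2") %in% feature_sets)) {
    paired <- pair_accuracies(tab, "feature_set", c("FS1", "FS2"),
                              c("dataset", "classifier"))
    comparisons$fs1_vs_fs2 <- c(
      list(pairs = paired),
      report = list(wilcoxon_compare(paired$FS1, paired$FS2)))
  }
  if (all(c("DS1", "DS2") %in% names(segments))) {
    paired <- pair_accuracies(tab, "dataset", c("DS1", "DS2"),
                              c("feature_set", "classifier"))
    comparisons$ds1_vs_ds2 <- c(
      list(pairs = paired),
      report = list(wilcoxon_compare(paired$DS1, paired$DS2)))
  }

  structure(list(results = results, table = tab,
                 segment_counts = seg_counts,
                 aggregates = aggregates, comparisons = comparisons,
                 granularity = granularity, seed = as.integer(seed)),
            class = "condition_grid")
}

# Reshape the long accuracy table into paired columns of `levels` of
# `factor_var`, matched on the remaining factors `by`.
pair_accuracies <- function(tab, factor_var, levels, by) {
  a <- tab[tab[[factor_var]] == levels[1], , drop = FALSE]
  b <- tab[tab[[factor_var]] == levels[2], , drop = FALSE]
  key <- function(d) do.call(paste, c(d[by], sep = "|"))
  b <- b[match(key(a), key(b)), , drop = FALSE]
  out <- data.frame(a[by], x1 = a$accuracy, x2 = b$accuracy,
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "x1"] <- levels[1]
  names(out)[names(out) == "x2"] <- levels[2]
  out
}

#' @export
print.condition_grid <- function(x, ...) {
  cat(sprintf("<condition_grid> %d conditions, leave-one-%s-out\n",
              nrow(x$table), x$granularity))
  cat("  median accuracy by classifier:\n")
  ag <- x$aggregates$by_classifier
  for (i in seq_len(nrow(ag))) {
    cat(sprintf("    %-4s %.1f%%\n", ag$level[i], 100 * ag$median_accuracy[i]))
  }
  for (nm in names(x$comparisons)) {
    rep <- x$comparisons[[nm]]$report
    cat(sprintf("  %s: p = %.4g (%s)\n", nm, rep$p_value, rep$method))
  }
  invisible(x)
}
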