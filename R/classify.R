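#' Classifier hyperparameter defaults
#'
#' Fixed, documented defaults for the five classifier families; no tuning is
#' performed anywhere in the package, so results are reproducible from the
#' seed alone. DT grows an unpruned tree (`cp = 0`, `minsplit = 2`); RF uses
#' 100 trees; SVM a radial-basis kernel with cost 1 (features are
#' standardized beforehand, see [loocv()]); LDA has no tunables beyond the
#' default (no shrinkage); MLP is a single hidden layer trained to
#' convergence or `mlp_maxit` iterations, no early stopping, with a small
#' weight decay for numerical stability.
#'
#' @param rf_ntree Number of random-forest trees.
#' @param dt_cp,dt_minsplit rpart complexity and split controls.
#' @param svm_cost SVM soft-margin cost.
#' @param mlp_size Hidden-layer width.
#' @param mlp_decay Weight decay.
#' @param mlp_maxit Maximum training iterations.
#' @return A list of class `classifier_control`.
#' @export
classifier_control <- function(rf_ntree = 100,
                               dt_cp = 0, dt_minsplit = 2,
                               svm_cost = 1,
                               mlp_size = 16, mlp_decay = 0.01,
                               mlp_maxit = 150) {
  structure(list(rf_ntree = rf_ntree, dt_cp = dt_cp, dt_minsplit = dt_minsplit,
                 svm_cost = svm_cost, mlp_size = mlp_size,
                 mlp_decay = mlp_decay, mlp_maxit = mlp_maxit),
            class = "classifier_control")
}

#' Names of the supported classifier families
#' @return Character vector `c("DT", "RF", "SVM", "LDA", "MLP")`.
#' @export
classifier_names <- function() c("DT", "RF", "SVM", "LDA", "MLP")

# Fit one classifier on (x_train, y_train) and predict x_test.
# y_train is a factor with levels 0:5 (unused levels dropped before fitting,
# restored in the returned factor). Feature standardization (z-score fit on
# the training rows only) is applied for the scale-sensitive families.
fit_predict <- function(classifier, x_train, y_train, x_test, control) {
  y_fit <- droplevels(y_train)
  if (classifier %in% c("SVM", "LDA", "MLP")) {
    mu <- colMeans(x_train)
    sd <- apply(x_train, 2, stats::sd)
    sd[sd < 1e-12] <- 1
    x_train <- scale(x_train, center = mu, scale = sd)
    x_test <- scale(x_test, center = mu, scale = sd)
  }
  pred <- switch(
    classifier,
    DT = {
      df <- data.frame(.y = y_fit, x_train, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            cp = control$dt_cp, minsplit = control$dt_minsplit,
                            xval = 0))
      predict(fit, newdata = as.data.frame(x_test), type = "class")
    },
    RF = {
      fit <- randomForest::randomForest(x = x_train, y = y_fit,
                                        ntree = control$rf_ntree)
      predict(fit, newdata = x_test)
    },
    SVM = {
      fit <- e1071::svm(x = x_train, y = y_fit, kernel = "radial",
                        cost = control$svm_cost, scale = FALSE)
      predict(fit, newdata = x_test)
    },
    LDA = {
      fit <- suppressWarnings(MASS::lda(x = x_train, grouping = y_fit))
      predict(fit, newdata = x_test)$class
    },
    MLP = {
      targets <- nnet::class.ind(y_fit)
      fit <- nnet::nnet(x = x_train, y = targets, size = control$mlp_size,
                        decay = control$mlp_decay, maxit = control$mlp_maxit,
                        softmax = TRUE, trace = FALSE, MaxNWts = 50000)
      pr <- predict(fit, newdata = x_test)
      factor(colnames(pr)[max.col(pr, ties.method = "first")],
             levels = levels(y_fit))
    },
    stop("unknown classifier: ", classifier, call. = FALSE)
  )
  factor(as.character(pred), levels = levels(y_train))
}

#' Classification accuracy
#'
#' Fraction of predictions matching the true labels,
#' `sum(I(g(x) == ghat(x))) / N` with the indicator summed over all classes.
#'
#' @param true_labels,predicted_labels Equal-length nonempty vectors.
#' @return Fraction in \[0, 1\].
#' @examples
#' accuracy(c(0, 0, 1, 2), c(0, 1, 1, 1))  # 0.5
#' @export
accuracy <- function(true_labels, predicted_labels) {
  n <- length(true_labels)
  if (n == 0) stop("no labels", call. = FALSE)
  if (n != length(predicted_labels)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  sum(as.character(true_labels) == as.character(predicted_labels)) / n
}

#' Majority-class baseline accuracy
#'
#' Accuracy of a dummy classifier that always predicts the most frequent
#' label: the share of the majority class.
#'
#' @param labels Nonempty label vector.
#' @return Fraction in \[0, 1\].
#' @export
majority_class_accuracy <- function(labels) {
  if (length(labels) == 0) stop("no labels", call. = FALSE)
  max(table(labels)) / length(labels)
}

#' Leave-one-out cross-validation of a classifier on a feature matrix
#'
#' At `granularity = "subject"` (leave-one-subject-out, the default) each
#' fold holds out every segment of one subject, so no subject contributes to
#' both training and test; at `granularity = "segment"` each fold holds out
#' a single segment. Predictions are pooled over all folds into one
#' confusion matrix. Stochastic classifiers are seeded per fold from `seed`,
#' so results are deterministic. A fold whose training set lacks some class
#' (unavoidable for singleton classes such as MAS 4 under subject-level
#' folds) is permitted and recorded in the result's `folds_missing_class`.
#'
#' @param features Feature matrix from [feature_matrix()] (metadata columns
#'   plus numeric features).
#' @param classifier One of [classifier_names()].
#' @param granularity `"subject"` or `"segment"`.
#' @param seed Integer seed.
#' @param control A [classifier_control()].
#' @param condition Optional named list tagging the run (e.g. dataset and
#'   feature set), carried into the result.
#' @return An object of class `cv_result`: list with `condition`,
#'   `predictions` (data.frame of unit, subject_id, true, predicted),
#'   `accuracy`, `confusion` (6 x 6 matrix over labels 0-5), `per_class`
#'   (see [per_class_metrics()]) and `folds_missing_class`.
#' @export
loocv <- function(features, classifier = classifier_names(),
                  granularity = c("subject", "segment"), seed = 1L,
                  control = classifier_control(), condition = list()) {
  classifier <- match.arg(classifier)
  granularity <- match.arg(granularity)
  feat_cols <- setdiff(names(features), feature_meta_cols())
  x <- as.matrix(features[, feat_cols, drop = FALSE])
  y <- factor(features$mas_label, levels = mas_labels())
  units <- if (granularity == "subject") features$subject_id else seq_len(nrow(x))
  uniq <- unique(units)
  if (length(uniq) < 2) stop("need at least 2 held-out units", call. = FALSE)
  if (any(table(factor(features$mas_label)) < 1)) {
    stop("every class present must have at least one instance", call. = FALSE)
  }

  preds <- factor(rep(NA_character_, nrow(x)), levels = levels(y))
  missing_class_folds <- character(0)
  for (k in seq_along(uniq)) {
    test_idx <- which(units == uniq[k])
    train_idx <- setdiff(seq_len(nrow(x)), test_idx)
    y_train <- y[train_idx]
    absent <- setdiff(unique(as.character(y)), unique(as.character(y_train)))
    if (length(absent) > 0) {
      missing_class_folds <- c(missing_class_folds, as.character(uniq[k]))
    }
    set.seed(as.integer(seed) + k)
    if (length(unique(as.character(y_train))) == 1) {
      # degenerate fold: training collapsed to one class, predict it
      preds[test_idx] <- factor(as.character(y_train[1]), levels = levels(y))
    } else {
      preds[test_idx] <- fit_predict(classifier, x[train_idx, , drop = FALSE],
                                     y_train, x[test_idx, , drop = FALSE],
                                     control)
    }
  }

  confusion <- table(true = y, predicted = preds)
  res <- structure(list(
    condition = utils::modifyList(list(classifier = classifier,
                                       granularity = granularity), condition),
    predictions = data.frame(unit = units,
                             subject_id = features$subject_id,
                             true = y, predicted = preds,
                             stringsAsFactors = FALSE),
    accuracy = accuracy(y, preds),
    confusion = unclass(confusion),
    folds_missing_class = missing_class_folds
  ), class = "cv_result")
  res$per_class <- per_class_metrics(res)
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cond <- x$condition
  extra <- setdiff(names(cond), c("classifier", "granularity"))
  tag <- if (length(extra)) {
    paste0(" [", paste(unlist(cond[extra]), collapse = "/"), "]")
  } else ""
  cat(sprintf("<cv_result> %s%s, leave-one-%s-out: accuracy %.1f%% (n = %d)\n",
              cond$classifier, tag, cond$granularity,
              100 * x$accuracy, nrow(x$predictions)))
  if (length(x$folds_missing_class)) {
    cat("  folds trained without some class:",
        paste(x$folds_missing_class, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-class precision, recall and class accuracy
#'
#' From the pooled confusion matrix: `precision_k = TP_k / (TP_k + FP_k)`,
#' `recall_k = TP_k / (TP_k + FN_k)`, and a per-class accuracy defined as
#' the mean of precision and recall. Undefined ratios (zero denominator,
#' e.g. a class never predicted or absent from the truth) are reported as
#' `NA`, never as 0.
#'
#' @param cv_result A `cv_result` from [loocv()], or a bare confusion
#'   matrix.
#' @return data.frame with columns `label, mas_score, n_true, precision,
#'   recall, class_accuracy`.
#' @export
per_class_metrics <- function(cv_result) {
  cm <- if (is.matrix(cv_result)) cv_result else cv_result$confusion
  tp <- diag(cm)
  pred_tot <- colSums(cm)
  true_tot <- rowSums(cm)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, NA_real_)
  recall <- ifelse(true_tot > 0, tp / true_tot, NA_real_)
  labs <- if (!is.null(rownames(cm))) as.integer(rownames(cm)) else seq_len(nrow(cm)) - 1L
  scores <- if (all(labs %in% mas_labels())) mas_scores()[labs + 1] else as.character(labs)
  data.frame(label = labs, mas_score = scores, n_true = as.integer(true_tot),
             precision = unname(precision), recall = unname(recall),
             class_accuracy = unname((precision + recall) / 2),
             stringsAsFactors = FALSE)
}

#' Median of a set of accuracies
#'
#' Standard median (mean of the middle two values for even n), used to
#' summarize accuracies across conditions.
#'
#' @param accuracies Nonempty numeric vector.
#' @return Scalar median.
#' @export
median_accuracy <- function(accuracies) {
  if (length(accuracies) == 0) stop("empty accuracy list", call. = FALSE)
  stats::median(accuracies)
}
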