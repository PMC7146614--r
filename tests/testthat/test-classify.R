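test_that("accuracy is the fraction of matching labels", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(accuracy(c(1, 2, 3), c(2, 3, 1)), 0)
  expect_equal(accuracy(c(0, 0, 1, 2), c(0, 1, 1, 1)), 0.5)
  expect_error(accuracy(1:3, 1:2), "length")
  expect_error(accuracy(integer(0), integer(0)), "no labels")
})

test_that("majority baseline equals the majority-class share", {
  labs <- rep(0:5, times = c(51, 39, 21, 18, 12, 3))
  expect_equal(majority_class_accuracy(labs), 51 / 144)
  expect_equal(round(100 * majority_class_accuracy(labs), 1), 35.4)
})

test_that("per-class precision/recall match hand computation", {
  cm <- matrix(c(2, 0, 1, 3), 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
  pc <- per_class_metrics(cm)
  expect_equal(pc$precision, c(1, 0.75))
  expect_equal(pc$recall, c(2 / 3, 1))
  expect_equal(pc$class_accuracy, c((1 + 2 / 3) / 2, 0.875))
  # perfect predictions: all ones
  cm_perf <- diag(c(5, 3)); dimnames(cm_perf) <- list(c("0", "1"), c("0", "1"))
  expect_true(all(per_class_metrics(cm_perf)$precision == 1))
  expect_true(all(per_class_metrics(cm_perf)$recall == 1))
  # a class never predicted has undefined precision (NA, not 0)
  cm0 <- matrix(c(2, 1, 0, 0), 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
  pc0 <- per_class_metrics(cm0)
  expect_true(is.na(pc0$precision[2]))
  expect_true(!is.na(pc0$recall[2]))
})

test_that("median_accuracy follows the even-n convention", {
  expect_equal(median_accuracy(c(0.7, 0.8, 0.9)), 0.8)
  expect_equal(median_accuracy(c(0.6, 0.8)), 0.7)
  expect_equal(median_accuracy(0.42), 0.42)
  expect_error(median_accuracy(numeric(0)), "empty")
})

test_that("all five classifiers solve a separable problem under LOOCV", {
  fm <- separable_features(c(`0` = 4, `3` = 4))
  for (clf in classifier_names()) {
    res <- loocv(fm, clf, granularity = "subject", seed = 1)
    expect_equal(res$accuracy, 1, info = clf)
    expect_equal(sum(diag(res$confusion)), nrow(fm), info = clf)
  }
})

test_that("subject-level folds never split a subject and cover all units", {
  fm <- separable_features(c(`0` = 3, `2` = 3, `5` = 2), segs = 3)
  res <- loocv(fm, "DT", granularity = "subject", seed = 2)
  # one prediction per segment, units are the subjects
  expect_equal(nrow(res$predictions), nrow(fm))
  expect_equal(sort(unique(res$predictions$unit)), sort(unique(fm$subject_id)))
  # fold count equals number of subjects: each subject's segments are all
  # predicted (none NA), which requires exactly one held-out fold each
  expect_true(all(!is.na(res$predictions$predicted)))
  res_seg <- loocv(fm, "DT", granularity = "segment", seed = 2)
  expect_equal(length(unique(res_seg$predictions$unit)), nrow(fm))
})

test_that("accuracy equals trace(confusion)/sum(confusion)", {
  fm <- separable_features(c(`0` = 3, `1` = 3), scatter = 20, seed = 7)
  res <- loocv(fm, "LDA", granularity = "subject", seed = 3)
  expect_equal(res$accuracy, sum(diag(res$confusion)) / sum(res$confusion))
  # confusion row sums equal the true class counts
  expect_equal(unname(rowSums(res$confusion)[c("0", "1")]),
               unname(as.vector(table(fm$mas_label))))
})

test_that("folds that lose a singleton class are permitted and recorded", {
  fm <- separable_features(c(`0` = 3, `4` = 1), segs = 3)
  res <- loocv(fm, "RF", granularity = "subject", seed = 4)
  singleton <- unique(fm$subject_id[fm$mas_label == 4])
  expect_equal(res$folds_missing_class, singleton)
  # the singleton cannot be predicted correctly; others can
  keep <- res$predictions$true != "4"
  expect_equal(accuracy(res$predictions$true[keep], res$predictions$predicted[keep]), 1)
})

test_that("LOOCV is deterministic under a fixed seed", {
  fm <- separable_features(c(`0` = 3, `1` = 3), scatter = 5, seed = 9)
  r1 <- loocv(fm, "RF", granularity = "subject", seed = 5)
  r2 <- loocv(fm, "RF", granularity = "subject", seed = 5)
  expect_identical(r1$predictions$predicted, r2$predictions$predicted)
  r3 <- loocv(fm, "MLP", granularity = "subject", seed = 5)
  r4 <- loocv(fm, "MLP", granularity = "subject", seed = 5)
  expect_identical(r3$predictions$predicted, r4$predictions$predicted)
})

test_that("loocv rejects degenerate inputs", {
  fm <- separable_features(c(`0` = 1), segs = 3)
  expect_error(loocv(fm, "DT", granularity = "subject"), "at least 2")
})
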