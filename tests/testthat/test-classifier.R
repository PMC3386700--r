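# tiny labeled feature frames for classifier unit tests
make_frame <- function(x, group, features = paste0("V", seq_len(ncol(x)))) {
  colnames(x) <- features
  data.frame(sample_id = sprintf("s%03d", seq_len(nrow(x))), group = group,
             x, stringsAsFactors = FALSE, check.names = FALSE)
}

test_that("subset enumeration is exhaustive and canonically ordered", {
  expect_length(enumerate_subsets(10), 1023L)
  expect_length(enumerate_subsets(1), 1L)
  s3 <- enumerate_subsets(3)
  expect_length(s3, 7L)
  expect_equal(s3[[1]], 1L)
  expect_equal(s3[[7]], 1:3)
  # cardinality ascending, then lexicographic within cardinality
  expect_equal(lengths(s3), c(1, 1, 1, 2, 2, 2, 3))
  expect_equal(s3[4:6], list(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  expect_error(enumerate_subsets(21), "refused")
  expect_error(enumerate_subsets(0), "positive")
})

test_that("partition honors counts, disjointness and the seed", {
  fm <- make_frame(matrix(rnorm(100 * 2), 100), rep(c("a", "b"), each = 50))
  spec <- partition_spec("a", "b", 25, 25, 25, 25, seed = 42)
  pt <- partition(fm, spec)
  expect_equal(table(pt$train$group), table(pt$test$group))
  expect_equal(sum(pt$test$group == "a"), 25L)
  expect_length(intersect(pt$train$sample_id, pt$test$sample_id), 0L)
  expect_setequal(c(pt$train$sample_id, pt$test$sample_id), fm$sample_id)
  pt2 <- partition(fm, spec)
  expect_identical(pt, pt2)
  pt3 <- partition(fm, partition_spec("a", "b", 25, 25, 25, 25, seed = 43))
  expect_false(identical(pt$train$sample_id, pt3$train$sample_id))
  expect_error(
    partition(fm, partition_spec("a", "b", 40, 25, 25, 25, seed = 1)),
    "65 requested")
})

test_that("linear SVM separates separable data and respects its limits", {
  sep <- make_frame(matrix(c(rep(1, 10), rep(-1, 10))), rep(c("p", "n"), each = 10))
  m <- fit_linear_classifier(sep, "V1", "p", "n")
  expect_equal(evaluate(m, sep)$accuracy, 100)

  # identical rows with conflicting labels: at most half can be right
  conf <- make_frame(matrix(rep(0.5, 8)), rep(c("p", "n"), 4))
  m2 <- fit_linear_classifier(conf, "V1", "p", "n")
  expect_lte(evaluate(m2, conf)$accuracy, 50)

  expect_error(fit_linear_classifier(sep[sep$group == "p", ], "V1", "p", "n"),
               "both classes")
})

test_that("max-margin boundary matches the analytic solution on a symmetric set", {
  # positives at x1 = +1, negatives at x1 = -1 (x2 symmetric): the
  # max-margin separator is exactly x1 = 0
  xy <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  train <- make_frame(xy, c("p", "p", "n", "n"))
  m <- fit_linear_classifier(train, c("V1", "V2"), "p", "n")
  grid <- expand.grid(V1 = seq(-2, 2, by = 0.5), V2 = seq(-2, 2, by = 0.5))
  grid <- grid[grid$V1 != 0, ]
  pred <- predict(m, grid)
  expect_equal(pred, ifelse(grid$V1 > 0, "p", "n"), ignore_attr = TRUE)
})

test_that("confusion metrics match their defining formulas", {
  cm <- confusion_matrix(tp = 22, fp = 1, tn = 24, fn = 4)
  expect_equal(round(cm$accuracy, 2), 90.20)
  expect_equal(round(cm$sensitivity, 2), 84.62)
  expect_equal(round(cm$specificity, 2), 96.00)
  expect_equal(round(cm$mcc, 2), 0.81)

  expect_equal(confusion_matrix(10, 0, 10, 0)$mcc, 1)
  expect_equal(confusion_matrix(0, 10, 0, 10)$mcc, -1)
  # degenerate marginal: MCC falls back to 0 by convention
  expect_equal(confusion_matrix(0, 0, 10, 10)$mcc, 0)
  expect_error(confusion_matrix(-1, 0, 1, 0), "non-negative")

  # accuracy decomposes exactly into sensitivity and specificity
  cm2 <- confusion_matrix(tp = 17, fp = 10, tn = 15, fn = 9)
  n_pos <- cm2$tp + cm2$fn; n_neg <- cm2$tn + cm2$fp
  expect_equal(cm2$accuracy,
               (cm2$sensitivity * n_pos + cm2$specificity * n_neg) /
                 (n_pos + n_neg))
})

test_that("subset selection finds planted signal and obeys its tie-breaks", {
  set.seed(7)  # local fixture noise; selection itself is deterministic
  n <- 30
  x <- matrix(rnorm(n * 5), n)
  group <- rep(c("p", "n"), each = n / 2)
  x[group == "p", 3] <- x[group == "p", 3] + 4   # feature V3 carries the signal
  train <- make_frame(x, group)
  best <- select_best_subset(train, positive_group = "p", negative_group = "n")
  expect_true("V3" %in% best$subset)

  # a single candidate subset is selected trivially
  one <- select_best_subset(train, subsets = list("V2"), positive_group = "p",
                            negative_group = "n")
  expect_equal(one$subset, "V2")

  # perfectly separable on V3 alone: {V3} and {V3, V4} tie at 100% train
  # accuracy and MCC 1; the smaller subset wins
  sep <- train
  sep$V3 <- ifelse(group == "p", 1, -1)
  tie <- select_best_subset(sep, subsets = list(c("V3"), c("V3", "V4")),
                            positive_group = "p", negative_group = "n")
  expect_equal(tie$subset, "V3")
  # equal cardinality: earlier canonical order wins
  sep$V4 <- sep$V3
  tie2 <- select_best_subset(sep, subsets = list(c("V4"), c("V3")),
                             positive_group = "p", negative_group = "n")
  expect_equal(tie2$subset, "V4")
})

test_that("reported winner is optimal under exhaustive re-scan (5 features)", {
  wells <- generate_cohort(small_config(seed = 31, n_per_group = 10L, k = 5L))
  fm <- build_feature_matrix(wells)
  pt <- partition(fm, partition_spec("pancreas", "control", 5, 5, 5, 5, 77))
  best <- select_best_subset(pt$train, positive_group = "pancreas",
                             negative_group = "control")
  feats <- setdiff(names(fm), c("sample_id", "group"))
  for (s in enumerate_subsets(5)) {
    m <- fit_linear_classifier(pt$train, feats[s], "pancreas", "control")
    expect_lte(evaluate(m, pt$train)$accuracy, best$train_accuracy)
  }
})

test_that("repeated experiment has the contracted shape and determinism", {
  fm <- build_feature_matrix(generate_cohort(small_config(seed = 12)))
  exp1 <- run_repeated_experiment(fm, "pancreas", "control",
                                  n_repeats = 3, seeds = c(5, 6, 7))
  expect_s3_class(exp1, "subset_experiment")
  expect_equal(nrow(exp1$results), 3L)
  expect_true(all(nchar(exp1$results$selected_features) > 0))
  expect_true(all(exp1$results$mcc >= -1 & exp1$results$mcc <= 1))
  expect_true(all(exp1$results$accuracy >= 0 & exp1$results$accuracy <= 100))
  # metrics consistency identity on every row
  r <- exp1$results
  expect_equal(r$accuracy,
               (r$sensitivity * (r$tp + r$fn) + r$specificity * (r$tn + r$fp)) /
                 (r$tp + r$fn + r$tn + r$fp))
  # consensus is contained in every selected subset
  for (s in exp1$selected) expect_true(all(exp1$consensus %in% s))

  exp2 <- run_repeated_experiment(fm, "pancreas", "control",
                                  n_repeats = 3, seeds = c(5, 6, 7))
  expect_identical(exp1$results, exp2$results)
})

test_that("balanced sizing reproduces the 25-per-group split on 50+50", {
  fm <- make_frame(matrix(rnorm(100)), rep(c("p", "n"), each = 50))
  fm$V1[fm$group == "p"] <- fm$V1[fm$group == "p"] + 3
  exp1 <- run_repeated_experiment(fm, "p", "n", n_repeats = 1, seeds = 1)
  expect_equal(exp1$results$tp + exp1$results$fn, 25)
  expect_equal(exp1$results$tn + exp1$results$fp, 25)
})

test_that("table2 sizing yields the 26/25 and 26/26 test compositions", {
  fm <- build_feature_matrix(generate_cohort(default_cohort_config(seed = 3)))
  f4 <- fm[, c("sample_id", "group", "V1", "V3")]  # 2 features keep it cheap
  e1 <- run_repeated_experiment(f4, "pancreas", "control", n_repeats = 1,
                                seeds = 1, sizing = "table2")
  expect_equal(e1$results$tp + e1$results$fn, 26)
  expect_equal(e1$results$tn + e1$results$fp, 25)
  e2 <- run_repeated_experiment(f4, "stomach", "pancreas", n_repeats = 1,
                                seeds = 1, sizing = "table2")
  expect_equal(e2$results$tp + e2$results$fn, 26)
  expect_equal(e2$results$tn + e2$results$fp, 26)
})

test_that("internal cross-validation scoring is available behind a flag", {
  fm <- build_feature_matrix(generate_cohort(small_config(seed = 9,
                                                          n_per_group = 10L,
                                                          k = 3L)))
  cvless <- run_repeated_experiment(fm, "pancreas", "control", n_repeats = 1,
                                    seeds = 2)
  cved <- run_repeated_experiment(fm, "pancreas", "control", n_repeats = 1,
                                  seeds = 2, cv_folds = 5)
  expect_s3_class(cved, "subset_experiment")
  # CV training score is honest (not resubstitution-optimistic 100%)
  expect_lte(cved$results$train_accuracy, cvless$results$train_accuracy)
})
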