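#' Enumerate all non-empty feature subsets
#'
#' Canonical exhaustive enumeration used by the wrapper feature selection:
#' subsets ordered by cardinality ascending, then lexicographically by
#' sorted feature indices. A 10-feature panel yields 2^10 - 1 = 1023
#' subsets. Refuses more than 20 features (over a million subsets):
#' exhaustive search is the point of this method only while it is cheap;
#' larger panels call for a heuristic search, which is out of scope.
#'
#' @param n_features number of features (1..20).
#' @return list of integer index vectors in canonical order.
#' @export
#' @examples
#' length(enumerate_subsets(10))  # 1023
enumerate_subsets <- function(n_features) {
  check_that(is.numeric(n_features) && length(n_features) == 1L &&
               n_features >= 1 && n_features == round(n_features),
             "n_features must be a positive integer")
  check_that(n_features <= 20,
             "exhaustive enumeration refused for %d features (> 20); use a heuristic search",
             as.integer(n_features))
  n <- as.integer(n_features)
  unlist(lapply(seq_len(n), function(k) {
    m <- utils::combn(n, k)
    lapply(seq_len(ncol(m)), function(j) m[, j])
  }), recursive = FALSE)
}

#' Specify a random balanced train/test partition
#'
#' @param positive_group,negative_group clinical group labels; the
#'   positive group is the one Sensitivity refers to.
#' @param n_train_pos,n_train_neg,n_test_pos,n_test_neg per-group counts.
#' @param seed partition seed.
#' @export
partition_spec <- function(positive_group, negative_group,
                           n_train_pos, n_train_neg, n_test_pos, n_test_neg,
                           seed) {
  counts <- c(n_train_pos, n_train_neg, n_test_pos, n_test_neg)
  check_that(all(counts >= 1), "all partition counts must be >= 1")
  structure(list(positive_group = positive_group,
                 negative_group = negative_group,
                 n_train_pos = as.integer(n_train_pos),
                 n_train_neg = as.integer(n_train_neg),
                 n_test_pos = as.integer(n_test_pos),
                 n_test_neg = as.integer(n_test_neg),
                 seed = as.integer(seed)),
            class = "partition_spec")
}

# Sizing presets. "balanced" splits each group in half (25/25 for n = 50).
# "table2" uses train 24 / test 26 positives with 25/25 controls in
# cancer-vs-control comparisons and 24/26 in both groups otherwise — the
# composition implied by printed sensitivity/specificity denominators in
# the motivating study, kept as an alternative because it contradicts the
# stated 25/25 split and neither can be confirmed.
sizing_counts <- function(sizing, n_pos, n_neg, negative_group) {
  switch(sizing,
    balanced = list(ntp = n_pos %/% 2L, nsp = n_pos - n_pos %/% 2L,
                    ntn = n_neg %/% 2L, nsn = n_neg - n_neg %/% 2L),
    table2 = {
      check_that(n_pos >= 50 && n_neg >= 50,
                 "'table2' sizing needs 50 samples per group")
      if (identical(negative_group, "control")) {
        list(ntp = 24L, nsp = 26L, ntn = 25L, nsn = 25L)
      } else {
        list(ntp = 24L, nsp = 26L, ntn = 24L, nsn = 26L)
      }
    },
    stop(sprintf("unknown sizing preset '%s'", sizing), call. = FALSE))
}

#' Randomly partition a feature matrix into train and test sets
#'
#' Seeded uniform random split within each of the two groups, honoring the
#' requested counts; train and test are disjoint by construction.
#'
#' @param fm feature matrix (from [normalize_to_controls()]).
#' @param spec a [partition_spec()].
#' @return list with `train` and `test` data.frames.
#' @export
partition <- function(fm, spec) {
  stopifnot(inherits(spec, "partition_spec"))
  pos <- fm[fm$group == spec$positive_group, , drop = FALSE]
  neg <- fm[fm$group == spec$negative_group, , drop = FALSE]
  check_that(nrow(pos) >= spec$n_train_pos + spec$n_test_pos,
             "group '%s' has %d samples; %d requested", spec$positive_group,
             nrow(pos), spec$n_train_pos + spec$n_test_pos)
  check_that(nrow(neg) >= spec$n_train_neg + spec$n_test_neg,
             "group '%s' has %d samples; %d requested", spec$negative_group,
             nrow(neg), spec$n_train_neg + spec$n_test_neg)
  with_seed(spec$seed, {
    ip <- sample(nrow(pos))
    inn <- sample(nrow(neg))
    train <- rbind(pos[ip[seq_len(spec$n_train_pos)], , drop = FALSE],
                   neg[inn[seq_len(spec$n_train_neg)], , drop = FALSE])
    test <- rbind(
      pos[ip[spec$n_train_pos + seq_len(spec$n_test_pos)], , drop = FALSE],
      neg[inn[spec$n_train_neg + seq_len(spec$n_test_neg)], , drop = FALSE])
    rownames(train) <- rownames(test) <- NULL
    list(train = train, test = test)
  })
}

feature_names <- function(fm) setdiff(names(fm), c("sample_id", "group"))

#' Fit a linear-kernel SVM on a feature subset
#'
#' Thin wrapper over the LIBSVM linear-kernel solver
#' (\code{\link[e1071]{svm}}) restricted to the given feature subset.
#' Features enter as produced by the normalization chain, with no further
#' scaling; regularization defaults to the library's C = 1. The dual
#' solver is deterministic given its inputs.
#'
#' @param data labeled feature rows (feature matrix subset).
#' @param subset character vector of feature (vesicle) names, or integer
#'   indices into the feature columns.
#' @param positive_group,negative_group the two class labels.
#' @param c_param SVM cost parameter.
#' @return object of class `reactomics_svm`.
#' @export
fit_linear_classifier <- function(data, subset, positive_group,
                                  negative_group, c_param = 1) {
  feats <- feature_names(data)
  if (is.numeric(subset)) subset <- feats[subset]
  check_that(all(subset %in% feats), "unknown feature(s): %s",
             paste(setdiff(subset, feats), collapse = ", "))
  y <- factor(data$group, levels = c(negative_group, positive_group))
  check_that(all(!is.na(y)), "rows outside the two classes present")
  check_that(nlevels(droplevels(y)) == 2L,
             "training set must contain both classes")
  x <- as.matrix(data[, subset, drop = FALSE])
  model <- e1071::svm(x, y, kernel = "linear", cost = c_param,
                      scale = FALSE, type = "C-classification")
  structure(list(svm = model, subset = subset,
                 positive_group = positive_group,
                 negative_group = negative_group),
            class = "reactomics_svm")
}

#' @export
predict.reactomics_svm <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$subset, drop = FALSE])
  as.character(stats::predict(object$svm, x))
}

#' Confusion matrix and binary classification metrics
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return object of class `confusion_matrix` with fields `tp, fp, tn, fn`
#'   and derived `accuracy`, `sensitivity`, `specificity` (percent) and
#'   `mcc`. MCC follows the convention of 0 when any marginal factor of
#'   its denominator is zero.
#' @export
#' @examples
#' confusion_matrix(tp = 22, fp = 1, tn = 24, fn = 4)
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  check_that(all(counts >= 0) && all(counts == round(counts)),
             "confusion counts must be non-negative integers")
  n <- tp + fp + tn + fn
  check_that(n > 0, "empty confusion matrix")
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(marg == 0)) 0 else {
    (tp * tn - fp * fn) / sqrt(prod(marg))
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = 100 * (tp + tn) / n,
                 sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
                 mcc = mcc),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  MCC %.2f\n",
              x$accuracy, x$sensitivity, x$specificity, x$mcc))
  invisible(x)
}

#' Evaluate a fitted classifier on labeled rows
#'
#' @param model a `reactomics_svm`.
#' @param data labeled feature rows.
#' @return a [confusion_matrix()].
#' @export
evaluate <- function(model, data) {
  check_that(nrow(data) > 0, "no rows to evaluate")
  pred <- predict(model, data)
  pos <- model$positive_group
  truth_pos <- data$group == pos
  confusion_matrix(tp = sum(pred == pos & truth_pos),
                   fp = sum(pred == pos & !truth_pos),
                   tn = sum(pred != pos & !truth_pos),
                   fn = sum(pred != pos & truth_pos))
}

# resubstitution or k-fold CV score of one subset on the training set
score_subset <- function(train, subset, positive_group, negative_group,
                         c_param, cv_folds = NULL) {
  if (is.null(cv_folds)) {
    model <- fit_linear_classifier(train, subset, positive_group,
                                   negative_group, c_param)
    cm <- evaluate(model, train)
    list(accuracy = cm$accuracy, mcc = cm$mcc, model = model)
  } else {
    folds <- rep_len(seq_len(cv_folds), nrow(train))
    pred <- character(nrow(train))
    for (f in seq_len(cv_folds)) {
      hold <- folds == f
      m <- fit_linear_classifier(train[!hold, , drop = FALSE], subset,
                                 positive_group, negative_group, c_param)
      pred[hold] <- predict(m, train[hold, , drop = FALSE])
    }
    truth_pos <- train$group == positive_group
    cm <- confusion_matrix(tp = sum(pred == positive_group & truth_pos),
                           fp = sum(pred == positive_group & !truth_pos),
                           tn = sum(pred != positive_group & !truth_pos),
                           fn = sum(pred != positive_group & truth_pos))
    model <- fit_linear_classifier(train, subset, positive_group,
                                   negative_group, c_param)
    list(accuracy = cm$accuracy, mcc = cm$mcc, model = model)
  }
}

#' Exhaustive wrapper feature selection on the training set
#'
#' Fits one linear SVM per candidate feature subset and scores it on the
#' training samples themselves (resubstitution, the default) or by
#' internal k-fold cross-validation. The winner is chosen by training
#' accuracy, ties broken by training MCC, then by fewer features, then by
#' canonical enumeration order — a total order, so selection is fully
#' deterministic. Note that resubstitution scoring is deliberately
#' faithful to the wrapper protocol this package validates; it is prone to
#' optimistic training estimates, which is why all quality claims rest on
#' the held-out test set.
#'
#' @param train labeled training rows.
#' @param subsets list of subsets from [enumerate_subsets()] (indices into
#'   the feature columns) or of feature-name vectors; defaults to all
#'   non-empty subsets.
#' @param positive_group,negative_group class labels.
#' @param c_param SVM cost.
#' @param cv_folds `NULL` for resubstitution scoring (default), or an
#'   integer number of folds.
#' @return list: `subset` (feature names), `model`, `train_accuracy`,
#'   `train_mcc`.
#' @export
select_best_subset <- function(train, subsets = NULL, positive_group,
                               negative_group, c_param = 1,
                               cv_folds = NULL) {
  feats <- feature_names(train)
  if (is.null(subsets)) subsets <- enumerate_subsets(length(feats))
  check_that(length(subsets) > 0, "no candidate subsets")
  best <- NULL
  n_failed <- 0L
  for (s in subsets) {
    nm <- if (is.numeric(s)) feats[s] else s
    sc <- tryCatch(
      score_subset(train, nm, positive_group, negative_group, c_param,
                   cv_folds),
      error = function(e) NULL)
    if (is.null(sc)) {
      n_failed <- n_failed + 1L
      next
    }
    # canonical order makes "first strict improvement" implement the
    # accuracy > MCC > fewer-features > earlier-order tie-break
    if (is.null(best) || sc$accuracy > best$train_accuracy ||
        (sc$accuracy == best$train_accuracy && sc$mcc > best$train_mcc)) {
      best <- list(subset = nm, model = sc$model,
                   train_accuracy = sc$accuracy, train_mcc = sc$mcc)
    }
  }
  if (n_failed > 0L) {
    warning(sprintf("%d subset(s) failed to fit and were skipped", n_failed),
            call. = FALSE)
  }
  check_that(!is.null(best), "no subset could be fitted")
  best
}

#' Repeated random-partition classification experiment
#'
#' The full binary experiment for one pair of clinical groups: for each
#' repeat, randomly partition both groups into balanced train/test sets,
#' run exhaustive subset selection with a linear SVM on the training set,
#' and evaluate the winning model on the held-out test set. Features
#' selected in every repeat form the consensus set.
#'
#' @param fm feature matrix.
#' @param positive_group,negative_group groups to compare (sensitivity
#'   refers to `positive_group`).
#' @param n_repeats number of random partitions.
#' @param seeds integer vector of per-repeat partition seeds (length
#'   `n_repeats`).
#' @param sizing `"balanced"` (default: each group split in half) or
#'   `"table2"`.
#' @param c_param SVM cost.
#' @param cv_folds see [select_best_subset()].
#' @return object of class `subset_experiment`: `results` (one row per
#'   repeat: selected features, train/test accuracy, sensitivity,
#'   specificity, MCC, confusion counts), `selected` (list of feature
#'   sets), `consensus`, plus the call parameters.
#' @export
run_repeated_experiment <- function(fm, positive_group, negative_group,
                                    n_repeats = 5L, seeds = NULL,
                                    sizing = "balanced", c_param = 1,
                                    cv_folds = NULL) {
  check_that(n_repeats >= 1, "n_repeats must be >= 1")
  if (is.null(seeds)) seeds <- seq_len(n_repeats)
  check_that(length(seeds) == n_repeats,
             "need one seed per repeat (%d != %d)", length(seeds), n_repeats)
  n_pos <- sum(fm$group == positive_group)
  n_neg <- sum(fm$group == negative_group)
  check_that(n_pos > 0 && n_neg > 0, "group(s) '%s'/'%s' absent from data",
             positive_group, negative_group)
  sz <- sizing_counts(sizing, n_pos, n_neg, negative_group)
  subsets <- enumerate_subsets(length(feature_names(fm)))

  rows <- vector("list", n_repeats)
  selected <- vector("list", n_repeats)
  for (i in seq_len(n_repeats)) {
    spec <- partition_spec(positive_group, negative_group,
                           sz$ntp, sz$ntn, sz$nsp, sz$nsn, seeds[i])
    pt <- partition(fm, spec)
    best <- select_best_subset(pt$train, subsets, positive_group,
                               negative_group, c_param, cv_folds)
    cm <- evaluate(best$model, pt$test)
    selected[[i]] <- best$subset
    rows[[i]] <- data.frame(
      rep = i, seed = seeds[i],
      selected_features = paste(best$subset, collapse = "+"),
      n_features = length(best$subset),
      train_accuracy = best$train_accuracy, train_mcc = best$train_mcc,
      accuracy = cm$accuracy, sensitivity = cm$sensitivity,
      specificity = cm$specificity, mcc = cm$mcc,
      tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
      stringsAsFactors = FALSE)
  }
  structure(list(positive_group = positive_group,
                 negative_group = negative_group,
                 results = do.call(rbind, rows),
                 selected = selected,
                 consensus = Reduce(intersect, selected),
                 seeds = seeds, sizing = sizing, c_param = c_param),
            class = "subset_experiment")
}

#' @export
print.subset_experiment <- function(x, ...) {
  cat(sprintf("Binary classification: %s (positive) vs %s\n",
              x$positive_group, x$negative_group))
  df <- x$results[, c("rep", "selected_features", "accuracy",
                      "sensitivity", "specificity", "mcc")]
  df[, 3:5] <- round(df[, 3:5], 2)
  df$mcc <- round(df$mcc, 2)
  print(df, row.names = FALSE)
  cat("consensus features:",
      if (length(x$consensus)) paste(x$consensus, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}
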