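#' Chance probability of a correct guess on a test set
#'
#' The chance model for classifier accuracy: a guesser that always emits
#' the majority class of the test set is right with probability equal to
#' the majority-class proportion (26/51 for a 26 + 25 split, 0.5 for a
#' balanced one).
#'
#' @param labels class labels of the test set (two classes).
#' @return majority-class proportion.
#' @export
chance_probability <- function(labels) {
  tab <- table(labels)
  check_that(length(tab) == 2L,
             "test set must contain exactly two classes (found %d)",
             length(tab))
  max(tab) / sum(tab)
}

#' Exact binomial upper-tail probability
#'
#' P(X >= k) for X ~ Binomial(n, p0), computed by stable log-space
#' summation of the exact terms — no normal approximation. Used to ask how
#' likely a chance classifier is to reach an observed test accuracy at
#' least once.
#'
#' @param k successes (0..n); the tail is inclusive.
#' @param n trials.
#' @param p0 success probability, strictly inside (0, 1).
#' @return P(X >= k) in (0, 1].
#' @export
#' @examples
#' binomial_tail_p(43, 51, 26/51)  # about 7e-7
binomial_tail_p <- function(k, n, p0) {
  check_that(length(k) == 1 && length(n) == 1 && length(p0) == 1,
             "scalar arguments required")
  check_that(n >= 1 && n == round(n) && k == round(k) && k >= 0 && k <= n,
             "need integers 0 <= k <= n")
  check_that(p0 > 0 && p0 < 1, "p0 must lie strictly in (0, 1)")
  if (k == 0) return(1)
  i <- k:n
  exp(logsumexp(lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)))
}

#' Binomial chance-accuracy significance of a classification experiment
#'
#' For each repeat of a [run_repeated_experiment()] result, computes the
#' exact probability that a chance classifier (majority-class guessing at
#' the test set's chance probability) scores at least as many correct test
#' predictions as the model did.
#'
#' @param experiment a `subset_experiment`.
#' @return data.frame: per repeat `n_test`, `k_correct`, `chance_p`,
#'   `p_value`, `method`.
#' @export
experiment_significance <- function(experiment) {
  stopifnot(inherits(experiment, "subset_experiment"))
  r <- experiment$results
  n_test <- r$tp + r$fp + r$tn + r$fn
  n_pos <- r$tp + r$fn
  n_neg <- r$tn + r$fp
  k <- r$tp + r$tn
  p0 <- pmax(n_pos, n_neg) / n_test
  data.frame(
    rep = r$rep, n_test = n_test, k_correct = k, chance_p = p0,
    p_value = vapply(seq_along(k),
                     function(i) binomial_tail_p(k[i], n_test[i], p0[i]),
                     numeric(1)),
    method = "exact_binomial", stringsAsFactors = FALSE)
}

#' Label-shuffle null experiment
#'
#' The permutation control for the whole pipeline: group labels of the
#' feature matrix are reassigned uniformly at random (preserving label
#' counts across the full cohort), and the complete binary experiment —
#' partitioning, exhaustive subset selection on the training set,
#' evaluation on the test set — is re-run on the shuffled data. With
#' labels carrying no information, the best classifiers' test MCC should
#' scatter around zero.
#'
#' @param fm feature matrix.
#' @param positive_group,negative_group groups to compare after shuffling.
#' @param n_shuffles number of label permutations.
#' @param seeds one seed per shuffle (drives both the permutation and the
#'   partition); defaults to `1:n_shuffles`.
#' @param sizing,c_param,cv_folds as in [run_repeated_experiment()].
#' @return object of class `shuffle_null`: per-shuffle test MCC and
#'   accuracy, with mean/SD summary.
#' @export
run_shuffle_null <- function(fm, positive_group, negative_group,
                             n_shuffles = 20L, seeds = NULL,
                             sizing = "balanced", c_param = 1,
                             cv_folds = NULL) {
  check_that(n_shuffles >= 1, "n_shuffles must be >= 1")
  if (is.null(seeds)) seeds <- seq_len(n_shuffles)
  check_that(length(seeds) == n_shuffles, "need one seed per shuffle")
  subsets <- enumerate_subsets(length(feature_names(fm)))
  mcc <- accuracy <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    res <- with_seed(seeds[s], {
      shuffled <- fm
      shuffled$group <- sample(fm$group)   # count-preserving permutation
      part_seed <- sample.int(.Machine$integer.max, 1)
      list(fm = shuffled, part_seed = part_seed)
    })
    exp1 <- run_repeated_experiment(res$fm, positive_group, negative_group,
                                    n_repeats = 1L, seeds = res$part_seed,
                                    sizing = sizing, c_param = c_param,
                                    cv_folds = cv_folds)
    mcc[s] <- exp1$results$mcc
    accuracy[s] <- exp1$results$accuracy
  }
  structure(list(positive_group = positive_group,
                 negative_group = negative_group,
                 n_shuffles = n_shuffles, seeds = seeds,
                 mcc = mcc, accuracy = accuracy,
                 mean_mcc = mean(mcc), sd_mcc = stats::sd(mcc)),
            class = "shuffle_null")
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf(
    "Label-shuffle null (%s vs %s, %d shuffles): mean test MCC %.3f (SD %.3f)\n",
    x$positive_group, x$negative_group, x$n_shuffles, x$mean_mcc, x$sd_mcc))
  invisible(x)
}
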