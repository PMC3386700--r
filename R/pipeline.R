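#' Configure an end-to-end reactomics run
#'
#' Bundles everything a full run needs: where the plate data comes from
#' (a CSV path or a synthetic-cohort configuration), which pairwise group
#' comparisons to classify, the seeds for every source of randomness
#' (no wall-clock entropy anywhere), and the experiment parameters.
#'
#' @param plates_path path to a plate CSV, or `NULL` to simulate.
#' @param synthetic a [synthetic_config()] used when `plates_path` is
#'   `NULL`; defaults to [default_cohort_config()] reseeded from `seed`.
#' @param comparisons list of `c(positive_group, negative_group)` pairs.
#' @param control_group label of the healthy-control group used for
#'   normalization.
#' @param n_repeats partitions per comparison.
#' @param seed base seed; per-repeat partition seeds and shuffle seeds are
#'   derived from it deterministically unless given explicitly.
#' @param partition_seeds optional matrix-like list of explicit per-repeat
#'   seeds, one integer vector per comparison.
#' @param n_shuffles label-shuffle repetitions per comparison (0 = skip).
#' @param sizing,c_param,cv_folds see [run_repeated_experiment()].
#' @param replicate_count replicates per serum when reading a plate CSV.
#' @param out_dir if non-`NULL`, CSV/JSON outputs are written there.
#' @return a validated `run_config` list.
#' @export
run_config <- function(plates_path = NULL, synthetic = NULL,
                       comparisons = list(c("pancreas", "control"),
                                          c("stomach", "control"),
                                          c("stomach", "pancreas")),
                       control_group = "control", n_repeats = 5L,
                       seed = 1L, partition_seeds = NULL,
                       n_shuffles = 0L, sizing = "balanced", c_param = 1,
                       cv_folds = NULL, replicate_count = 3L,
                       out_dir = NULL) {
  check_that(is.null(plates_path) || file.exists(plates_path),
             "plates_path does not exist: %s", plates_path %||% "")
  if (is.null(plates_path) && is.null(synthetic)) {
    synthetic <- default_cohort_config(seed = seed)
  }
  check_that(length(comparisons) >= 1, "at least one comparison required")
  for (cmp in comparisons) {
    check_that(length(cmp) == 2L && !anyDuplicated(cmp),
               "each comparison must name two distinct groups")
  }
  if (!is.null(partition_seeds)) {
    check_that(length(partition_seeds) == length(comparisons) &&
                 all(lengths(partition_seeds) == n_repeats),
               "partition_seeds must hold %d seeds per comparison",
               n_repeats)
  }
  structure(list(plates_path = plates_path, synthetic = synthetic,
                 comparisons = comparisons, control_group = control_group,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 partition_seeds = partition_seeds,
                 n_shuffles = as.integer(n_shuffles), sizing = sizing,
                 c_param = c_param, cv_folds = cv_folds,
                 replicate_count = as.integer(replicate_count),
                 out_dir = out_dir),
            class = "run_config")
}

comparison_tag <- function(cmp) paste(cmp[1], "vs", cmp[2], sep = "_")

#' Run the full reactomics pipeline
#'
#' Executes simulate/read, \%FCR aggregation, cross-plate
#' standardization, control normalization, repeated subset-SVM
#' classification for every configured comparison, binomial
#' chance-accuracy significance, and (optionally) the label-shuffle null.
#' Every quantity in the report is reproducible from the configuration
#' and its seeds alone. When `out_dir` is set, writes `features.csv`, one
#' `results_<pos>_vs_<neg>.csv` per comparison and a `summary.json`.
#'
#' @param config a [run_config()].
#' @return a `reactomics_report`: list with the feature matrix,
#'   per-comparison `subset_experiment`s, significance tables and shuffle
#'   nulls.
#' @export
#' @examples
#' \donttest{
#' cfg <- default_cohort_config(seed = 11)
#' cfg$n_per_group <- 12L
#' cfg$panel <- cfg$panel[1:4, ]
#' cfg$group_effect <- cfg$group_effect[, 1:4]
#' report <- run_reactomics(run_config(synthetic = cfg, n_repeats = 2L))
#' report$experiments$pancreas_vs_control
#' }
run_reactomics <- function(config) {
  stopifnot(inherits(config, "run_config"))
  wells <- if (is.null(config$plates_path)) {
    generate_cohort(config$synthetic)
  } else {
    read_plates(config$plates_path,
                replicate_count = config$replicate_count)
  }
  groups_present <- setdiff(unique(wells$group), "none")
  for (cmp in config$comparisons) {
    missing <- setdiff(cmp, groups_present)
    check_that(length(missing) == 0L,
               "comparison references unknown group(s): %s",
               paste(missing, collapse = ", "))
  }

  fm <- build_feature_matrix(wells, control_group = config$control_group)

  experiments <- list()
  significance <- list()
  shuffles <- list()
  for (ci in seq_along(config$comparisons)) {
    cmp <- config$comparisons[[ci]]
    tag <- comparison_tag(cmp)
    seeds <- if (!is.null(config$partition_seeds)) {
      config$partition_seeds[[ci]]
    } else {
      # distinct, reproducible, well below 2^31
      config$seed + 1000L * ci + seq_len(config$n_repeats)
    }
    exp <- run_repeated_experiment(fm, cmp[1], cmp[2],
                                   n_repeats = config$n_repeats,
                                   seeds = seeds, sizing = config$sizing,
                                   c_param = config$c_param,
                                   cv_folds = config$cv_folds)
    experiments[[tag]] <- exp
    significance[[tag]] <- experiment_significance(exp)
    if (config$n_shuffles > 0L) {
      shuffles[[tag]] <- run_shuffle_null(
        fm, cmp[1], cmp[2], n_shuffles = config$n_shuffles,
        seeds = config$seed + 20000L * ci + seq_len(config$n_shuffles),
        sizing = config$sizing, c_param = config$c_param,
        cv_folds = config$cv_folds)
    }
  }

  report <- structure(list(config = config, feature_matrix = fm,
                           experiments = experiments,
                           significance = significance,
                           shuffles = shuffles),
                      class = "reactomics_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$feature_matrix,
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  summary <- list()
  for (tag in names(report$experiments)) {
    exp <- report$experiments[[tag]]
    res <- merge(exp$results,
                 report$significance[[tag]][, c("rep", "p_value")],
                 by = "rep")
    utils::write.csv(res, file.path(out_dir, paste0("results_", tag, ".csv")),
                     row.names = FALSE)
    summary[[tag]] <- list(
      consensus_features = exp$consensus,
      mean_test_accuracy = mean(exp$results$accuracy),
      mean_test_mcc = mean(exp$results$mcc),
      p_values = report$significance[[tag]]$p_value)
    if (!is.null(report$shuffles[[tag]])) {
      summary[[tag]]$shuffle_mean_mcc <- report$shuffles[[tag]]$mean_mcc
      summary[[tag]]$shuffle_sd_mcc <- report$shuffles[[tag]]$sd_mcc
    }
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.reactomics_report <- function(x, ...) {
  cat(sprintf("reactomics run: %d samples x %d vesicle features\n",
              nrow(x$feature_matrix),
              length(feature_names(x$feature_matrix))))
  for (tag in names(x$experiments)) {
    cat("\n")
    print(x$experiments[[tag]])
    p <- x$significance[[tag]]$p_value
    cat(sprintf("binomial chance-accuracy p: %s\n",
                paste(signif(p, 2), collapse = ", ")))
    if (!is.null(x$shuffles[[tag]])) print(x$shuffles[[tag]])
  }
  invisible(x)
}
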