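#' Percentage fluorescent chromatic response
#'
#' The core chromatic readout of a lipid/PDA detector:
#' \deqn{\%FCR = 100 (Em_i - Em_c) / (Em_r - Em_c)}
#' where `em_c` is the background fluorescence of unexposed blue-phase
#' vesicles, `em_i` the fluorescence after incubation with the tested
#' sample and `em_r` the maximal fluorescence of fully converted red-phase
#' vesicles (heat control). The value is not clipped: noise can push it
#' slightly outside \[0, 100\]. The formula cancels any affine map applied
#' to all three emissions, which is what makes per-plate controls remove
#' plate gain/offset artifacts.
#'
#' @param em_i,em_c,em_r emissions (vectorized over `em_i`).
#' @return \%FCR on the 0-100 scale (unbounded under noise).
#' @export
#' @examples
#' compute_fcr(35, em_c = 10, em_r = 110)  # 25
compute_fcr <- function(em_i, em_c, em_r) {
  check_that(all(em_r > em_c),
             "degenerate plate: red-phase emission (%g) must exceed blue-phase background (%g)",
             min(em_r), max(em_c))
  100 * (em_i - em_c) / (em_r - em_c)
}

#' Per-well \%FCR without replicate aggregation
#'
#' Computes \%FCR for every sample/standard well against the plate's own
#' color-control estimates (mean of the negative / positive control
#' wells). Used for repeatability (RSD) assays where individual repeats
#' matter.
#'
#' @param wells validated cohort well data.
#' @return data.frame with one row per sample/standard well:
#'   `plate_id, vesicle_id, well, sample_id, role, group, fcr, em_c, em_r`.
#' @export
well_fcr <- function(wells) {
  out <- lapply(split(wells, wells$plate_id), function(p) {
    em_c <- mean(p$emission[p$role == "neg_control"])
    em_r <- mean(p$emission[p$role == "pos_control"])
    check_that(em_r > em_c,
               "degenerate plate '%s': Em_r estimate (%.3g) <= Em_c estimate (%.3g)",
               p$plate_id[1], em_r, em_c)
    s <- p[p$role %in% c("sample", "standard"), , drop = FALSE]
    data.frame(plate_id = s$plate_id, vesicle_id = s$vesicle_id,
               well = s$well, sample_id = s$sample_id, role = s$role,
               group = s$group, fcr = compute_fcr(s$emission, em_c, em_r),
               em_c = em_c, em_r = em_r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Aggregate replicate wells into per-serum \%FCR
#'
#' For each plate, estimates `Em_c` and `Em_r` as the means of the
#' negative and positive color-control wells, computes per-well \%FCR and
#' averages over each serum's replicate wells. Because \%FCR is invariant
#' to any affine distortion applied to the whole plate (controls
#' included), plate gain/offset artifacts cancel at this stage.
#'
#' @param wells validated cohort well data (one or many plates).
#' @return an FCR table: one row per (sample, vesicle, plate) with columns
#'   `plate_id, vesicle_id, sample_id, role, group, fcr, em_c, em_r`.
#' @export
aggregate_plates <- function(wells) {
  wf <- well_fcr(wells)
  key <- interaction(wf$plate_id, wf$sample_id, drop = TRUE)
  agg <- lapply(split(wf, key), function(d) {
    data.frame(plate_id = d$plate_id[1], vesicle_id = d$vesicle_id[1],
               sample_id = d$sample_id[1], role = d$role[1],
               group = d$group[1], fcr = mean(d$fcr),
               em_c = d$em_c[1], em_r = d$em_r[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$vesicle_id, out$plate_id, out$sample_id), ]
  rownames(out) <- NULL
  out
}

#' Standardize \%FCR scales across plates of the same vesicle
#'
#' Plates measuring the same detector vesicle are aligned through the
#' standardization sera present on every plate: for each vesicle, the
#' cross-plate reference for a standard is the mean of its \%FCR over all
#' plates; each plate's five standard values are then mapped onto the
#' references by least-squares affine regression (`ref ~ a + b * plate`),
#' and the fitted transform is applied to all of the plate's \%FCR values.
#' Vesicles measured on a single plate pass through unchanged. If a
#' plate's standards are degenerate (fewer than two distinct values), an
#' offset-only correction is used with a warning.
#'
#' @param fcr an FCR table from [aggregate_plates()].
#' @return the FCR table with standardized `fcr` values.
#' @export
standardize_across_plates <- function(fcr) {
  parts <- split(fcr, fcr$vesicle_id)
  out <- lapply(parts, function(fv) {
    plates <- unique(fv$plate_id)
    if (length(plates) < 2L) return(fv)
    std <- fv[fv$role == "standard", , drop = FALSE]
    std_ids <- sort(unique(std$sample_id))
    check_that(length(std_ids) >= 1L,
               "vesicle '%s': multiple plates but no standardization sera",
               fv$vesicle_id[1])
    per_plate <- lapply(plates, function(pid) {
      x <- std[std$plate_id == pid, ]
      check_that(setequal(x$sample_id, std_ids),
                 "plate '%s' lacks part of the standardization set", pid)
      x$fcr[match(std_ids, x$sample_id)]
    })
    refs <- rowMeans(do.call(cbind, per_plate))
    for (i in seq_along(plates)) {
      x <- per_plate[[i]]
      if (stats::sd(x) == 0) {
        warning(sprintf(
          "plate '%s': standards have zero variance; offset-only correction",
          plates[i]), call. = FALSE)
        a <- mean(refs) - mean(x); b <- 1
      } else {
        fit <- stats::lm.fit(cbind(1, x), refs)
        a <- fit$coefficients[1]; b <- fit$coefficients[2]
      }
      sel <- fv$plate_id == plates[i]
      fv$fcr[sel] <- a + b * fv$fcr[sel]
    }
    fv
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Normalize \%FCR to the plate's clinical control group and build the
#' feature matrix
#'
#' Within every plate, the mean \%FCR of the healthy-control clinical
#' samples on that plate is subtracted from each sample's \%FCR and the
#' result is divided by their standard deviation (sample SD, n-1). The
#' z-like values are then assembled into a samples-by-vesicles feature
#' matrix; each normalized \%FCR is one classification feature.
#' Standardization sera and color controls do not enter the matrix.
#' Samples lacking a measurement for any vesicle are dropped with a
#' warning rather than imputed.
#'
#' @param fcr an FCR table (ideally after [standardize_across_plates()]).
#' @param control_group label of the healthy-control clinical group.
#' @return a feature matrix data.frame: `sample_id`, `group`, then one
#'   numeric column per vesicle.
#' @export
normalize_to_controls <- function(fcr, control_group = "control") {
  samp <- fcr[fcr$role == "sample", , drop = FALSE]
  check_that(nrow(samp) > 0L, "no clinical samples in FCR table")
  norm <- lapply(split(samp, samp$plate_id), function(p) {
    ctrl <- p$fcr[p$group == control_group]
    check_that(length(ctrl) >= 2L,
               "plate '%s' has %d control-group sample(s); >= 2 required for normalization",
               p$plate_id[1], length(ctrl))
    s <- stats::sd(ctrl)
    check_that(s > 0, "plate '%s': control-group %%FCR has zero variance",
               p$plate_id[1])
    p$fcr <- (p$fcr - mean(ctrl)) / s
    p
  })
  norm <- do.call(rbind, norm)

  vesicles <- unique(fcr$vesicle_id)
  ids <- unique(norm$sample_id)
  mat <- matrix(NA_real_, length(ids), length(vesicles),
                dimnames = list(ids, vesicles))
  mat[cbind(match(norm$sample_id, ids), match(norm$vesicle_id, vesicles))] <-
    norm$fcr
  complete <- stats::complete.cases(mat)
  if (any(!complete)) {
    warning(sprintf("dropping %d sample(s) with missing vesicle measurements: %s",
                    sum(!complete),
                    paste(utils::head(ids[!complete], 5L), collapse = ", ")),
            call. = FALSE)
    mat <- mat[complete, , drop = FALSE]
    ids <- ids[complete]
  }
  grp <- norm$group[match(ids, norm$sample_id)]
  fm <- data.frame(sample_id = ids, group = grp, mat,
                   stringsAsFactors = FALSE, check.names = FALSE,
                   row.names = NULL)
  fm <- fm[order(fm$sample_id), , drop = FALSE]
  rownames(fm) <- NULL
  fm
}

#' Full chromatic-response pipeline: wells to feature matrix
#'
#' Convenience chain: [aggregate_plates()] then
#' [standardize_across_plates()] then [normalize_to_controls()].
#'
#' @inheritParams normalize_to_controls
#' @param wells validated cohort well data.
#' @export
build_feature_matrix <- function(wells, control_group = "control") {
  normalize_to_controls(
    standardize_across_plates(aggregate_plates(wells)),
    control_group = control_group)
}

#' Repeatability of the chromatic assay (relative standard deviation)
#'
#' For a repeat assay (the same serum measured k times against one
#' vesicle), computes per-serum RSD = 100 x SD / mean of the repeated
#' \%FCR values, and their average — the assay's repeatability metric.
#'
#' @param fcr_repeats data.frame with columns `sample_id` and `fcr`,
#'   several rows per serum (e.g. from [well_fcr()]).
#' @return list with `per_serum` (named vector of RSDs, percent) and
#'   `average`.
#' @export
#' @examples
#' compute_rsd(data.frame(sample_id = "s1", fcr = c(40, 50, 60)))
compute_rsd <- function(fcr_repeats) {
  check_that(all(c("sample_id", "fcr") %in% names(fcr_repeats)),
             "need columns sample_id and fcr")
  per <- vapply(split(fcr_repeats$fcr, fcr_repeats$sample_id), function(x) {
    check_that(length(x) >= 2L, "each serum needs >= 2 repeats")
    m <- mean(x)
    check_that(abs(m) > .Machine$double.eps^0.5,
               "RSD undefined: mean %%FCR is zero")
    100 * stats::sd(x) / m
  }, numeric(1))
  list(per_serum = per, average = mean(per))
}
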