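#' Configure a synthetic plate cohort
#'
#' Builds and validates the generative model for a synthetic serum cohort
#' measured against a detector-vesicle panel on 96-well plates. Each serum
#' `s` in group `g` carries a latent true chromatic response
#' `f(s, v) ~ Normal(group_effect[g, v], serum_sd)` (truncated to
#' \[0, 100\]) for each vesicle `v`, and each replicate well reads
#' \deqn{gain \times (Em_c + f/100 (Em_r - Em_c) + \epsilon) + offset,}
#' with replicate noise `epsilon ~ Normal(0, replicate_sd (Em_r - Em_c)/100)`
#' and per-plate affine distortion `gain ~ Normal(1, plate_gain_sd)`,
#' `offset ~ Normal(0, plate_offset_sd)`. Negative/positive color-control
#' wells read the distorted `Em_c` / `Em_r`; the same five standardization
#' sera (with a latent response fixed per vesicle) appear on every plate.
#'
#' @param n_per_group sera per clinical group.
#' @param groups clinical group labels.
#' @param panel detector panel (see [default_panel()]).
#' @param group_effect numeric matrix of mean \%FCR, rows named by group,
#'   one column per panel vesicle, values in \[0, 100\].
#' @param em_c_mean,em_c_sd blue-phase background fluorescence (a.u.).
#' @param em_r_mean,em_r_sd red-phase maximal fluorescence (a.u.);
#'   `em_r_mean` must exceed `em_c_mean`.
#' @param serum_sd between-serum SD of latent \%FCR.
#' @param replicate_sd within-replicate noise SD, in \%FCR points.
#' @param plate_gain_sd,plate_offset_sd scales of the per-plate
#'   multiplicative/additive distortion.
#' @param replicate_count wells per serum per plate.
#' @param n_control_wells negative and positive color-control wells each.
#' @param standards identities of the standardization sera placed on every
#'   plate.
#' @param seed integer driving all randomness of [generate_cohort()].
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_group = 50L,
                             groups = c("control", "stomach", "pancreas"),
                             panel = default_panel(),
                             group_effect,
                             em_c_mean = 100, em_c_sd = 5,
                             em_r_mean = 1100, em_r_sd = 30,
                             serum_sd = 10, replicate_sd = 2,
                             plate_gain_sd = 0.05, plate_offset_sd = 5,
                             replicate_count = 3L, n_control_wells = 3L,
                             standards = paste0("STD", 1:5),
                             seed = 1L) {
  check_that(em_r_mean > em_c_mean,
             "em_r_mean (%g) must exceed em_c_mean (%g)", em_r_mean, em_c_mean)
  sds <- c(em_c_sd, em_r_sd, serum_sd, replicate_sd,
           plate_gain_sd, plate_offset_sd)
  check_that(all(sds >= 0), "all SD parameters must be >= 0")
  check_that(is.matrix(group_effect) && is.numeric(group_effect),
             "group_effect must be a numeric matrix")
  missing_g <- setdiff(groups, rownames(group_effect))
  check_that(length(missing_g) == 0L,
             "group(s) absent from group_effect: %s",
             paste(missing_g, collapse = ", "))
  check_that(ncol(group_effect) == nrow(panel),
             "group_effect needs one column per panel vesicle (%d)",
             nrow(panel))
  check_that(all(group_effect >= 0 & group_effect <= 100),
             "group_effect values must lie in [0, 100]")
  check_that(n_per_group >= 1 && replicate_count >= 1 && n_control_wells >= 1,
             "counts must be positive")
  check_that(length(standards) >= 1, "at least one standardization serum")
  colnames(group_effect) <- panel$vesicle_id
  cfg <- list(n_per_group = as.integer(n_per_group), groups = groups,
              panel = panel, group_effect = group_effect[groups, , drop = FALSE],
              em_c_mean = em_c_mean, em_c_sd = em_c_sd,
              em_r_mean = em_r_mean, em_r_sd = em_r_sd,
              serum_sd = serum_sd, replicate_sd = replicate_sd,
              plate_gain_sd = plate_gain_sd, plate_offset_sd = plate_offset_sd,
              replicate_count = as.integer(replicate_count),
              n_control_wells = as.integer(n_control_wells),
              standards = standards, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Default three-group cohort configuration
#'
#' The study conditions the package is validated against: 50 control,
#' 50 stomach-cancer and 50 pancreatic-cancer sera measured in triplicate
#' against the 10-vesicle default panel. Group mean responses encode the
#' qualitative clinical pattern: stomach-cancer sera react *below* control
#' on every vesicle, while pancreatic-cancer sera show a mixed response —
#' above control only on DMPC/Chl/PDA (1:1:3) and DMPE/PS/PDA (1:1:3)
#' (vesicles `V3` and `V5`) and at or below control elsewhere.
#'
#' @param seed cohort seed.
#' @return a `synthetic_config`.
#' @export
#' @examples
#' cfg <- default_cohort_config(seed = 7)
#' cfg$group_effect
default_cohort_config <- function(seed = 1L) {
  control <- c(55, 45, 50, 52, 48, 50, 47, 53, 44, 51)
  stomach <- control - c(4, 3, 3, 5, 3, 4, 2, 3, 4, 3)
  pancreas <- control + c(-8, -6, 14, -4, 14, -5, -2, -6, -3, -7)
  ge <- rbind(control = control, stomach = stomach, pancreas = pancreas)
  synthetic_config(group_effect = ge, seed = seed)
}

# sera the 96-well geometry allows per plate, after controls and standards
samples_per_plate <- function(cfg) {
  used <- 2L * cfg$n_control_wells + length(cfg$standards) * cfg$replicate_count
  free <- 96L - used
  check_that(free >= cfg$replicate_count,
             "plate layout leaves no room for samples (%d wells used)", used)
  free %/% cfg$replicate_count
}

well_coords <- function(n) {
  coords <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  check_that(n <= 96L, "plate capacity exceeded: %d wells", n)
  coords[seq_len(n)]
}

#' Generate a synthetic plate cohort
#'
#' Simulates well-level fluorescence for every (serum, vesicle) pair under
#' the model described in [synthetic_config()]. Sera are split across as
#' many plates per vesicle as the 96-well capacity requires; each plate
#' carries its own color controls and the full standardization-serum set,
#' and receives its own affine gain/offset distortion, so that cross-plate
#' standardization is exercised exactly as in a real multi-plate assay.
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return well-level data.frame in the plate CSV layout (see
#'   [read_plates()]); also carries the latent true \%FCR per serum and
#'   vesicle in `attr(, "latent")`.
#' @export
#' @examples
#' cfg <- default_cohort_config(seed = 42)
#' cfg$n_per_group <- 5L
#' wells <- generate_cohort(cfg)
#' head(wells)
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    vesicles <- cfg$panel$vesicle_id
    sera <- unlist(lapply(cfg$groups, function(g) {
      sprintf("%s_%03d", g, seq_len(cfg$n_per_group))
    }))
    serum_group <- rep(cfg$groups, each = cfg$n_per_group)
    names(serum_group) <- sera

    # latent %FCR: clinical sera per (serum, vesicle); standards fixed per
    # vesicle and shared by all plates of that vesicle
    latent <- matrix(NA_real_, length(sera), length(vesicles),
                     dimnames = list(sera, vesicles))
    # sd is applied by scaling standard normals so that the RNG stream is
    # identical across configs that differ only in noise scales
    for (s in sera) {
      mu <- cfg$group_effect[serum_group[[s]], ]
      latent[s, ] <- pmin(100, pmax(0, mu + cfg$serum_sd *
                                      stats::rnorm(length(vesicles))))
    }
    ctrl_mu <- if ("control" %in% rownames(cfg$group_effect)) {
      cfg$group_effect["control", ]
    } else {
      colMeans(cfg$group_effect)
    }
    std_latent <- matrix(NA_real_, length(cfg$standards), length(vesicles),
                         dimnames = list(cfg$standards, vesicles))
    for (s in cfg$standards) {
      std_latent[s, ] <- pmin(100, pmax(0, ctrl_mu + cfg$serum_sd *
                                          stats::rnorm(length(vesicles))))
    }

    per_plate <- samples_per_plate(cfg)
    out <- vector("list", length(vesicles))
    for (vi in seq_along(vesicles)) {
      v <- vesicles[vi]
      # stratified random plate assignment: shuffle within each group, then
      # deal round-robin over plates so every plate carries an even share
      # of every group (the plate design must leave >= 2 control sera per
      # plate for the downstream control normalization)
      by_group <- lapply(split(sera, serum_group[sera]), sample)
      n_plates <- ceiling(length(sera) / per_plate)
      while (sum(ceiling(lengths(by_group) / n_plates)) > per_plate) {
        n_plates <- n_plates + 1L
      }
      plate_of <- unlist(lapply(by_group, function(g) {
        rep_len(seq_len(n_plates), length(g))
      }), use.names = FALSE)
      batches <- split(unlist(by_group, use.names = FALSE), plate_of)
      plates <- vector("list", length(batches))
      for (bi in seq_along(batches)) {
        plate_id <- sprintf("%s_p%02d", v, bi)
        em_c <- cfg$em_c_mean + cfg$em_c_sd * stats::rnorm(1)
        em_r <- cfg$em_r_mean + cfg$em_r_sd * stats::rnorm(1)
        while (em_r <= em_c) {
          em_r <- cfg$em_r_mean + cfg$em_r_sd * stats::rnorm(1)
        }
        gain <- 1 + cfg$plate_gain_sd * stats::rnorm(1)
        while (gain <= 0) gain <- 1 + cfg$plate_gain_sd * stats::rnorm(1)
        offset <- cfg$plate_offset_sd * stats::rnorm(1)
        span <- em_r - em_c
        noise_sd <- cfg$replicate_sd * span / 100

        ids <- c(rep("", 2L * cfg$n_control_wells),
                 rep(cfg$standards, each = cfg$replicate_count),
                 rep(batches[[bi]], each = cfg$replicate_count))
        roles <- c(rep(c("neg_control", "pos_control"),
                       each = cfg$n_control_wells),
                   rep("standard", length(cfg$standards) * cfg$replicate_count),
                   rep("sample", length(batches[[bi]]) * cfg$replicate_count))
        grp <- ifelse(roles == "sample", serum_group[ids], "none")
        grp[is.na(grp)] <- "none"
        f <- numeric(length(ids))
        f[roles == "neg_control"] <- 0
        f[roles == "pos_control"] <- 100
        f[roles == "standard"] <- std_latent[ids[roles == "standard"], v]
        f[roles == "sample"] <- latent[ids[roles == "sample"], v]

        em <- gain * (em_c + f / 100 * span +
                        noise_sd * stats::rnorm(length(f))) + offset
        plates[[bi]] <- data.frame(
          plate_id = plate_id, vesicle_id = v,
          well = well_coords(length(ids)), sample_id = ids,
          role = roles, group = grp, emission = em,
          stringsAsFactors = FALSE)
      }
      out[[vi]] <- do.call(rbind, plates)
    }
    wells <- do.call(rbind, out)
    rownames(wells) <- NULL
    validate_plates(wells, replicate_count = cfg$replicate_count,
                    groups = cfg$groups)
    attr(wells, "latent") <- latent
    wells
  })
}

#' Randomly reassign clinical group labels across sample sera
#'
#' Permutes the group labels of the cohort's clinical sera uniformly at
#' random while preserving the count of each label; emissions, roles and
#' identities are untouched. This is the label-shuffle operation behind
#' the permutation-null validation of the classifier.
#'
#' @param wells cohort well data.
#' @param seed permutation seed.
#' @return `wells` with permuted `group` on sample wells.
#' @export
shuffle_group_labels <- function(wells, seed) {
  is_sample <- wells$role == "sample"
  check_that(any(is_sample), "cohort has no sample sera to shuffle")
  map <- unique(wells[is_sample, c("sample_id", "group")])
  new_groups <- with_seed(seed, sample(map$group))
  names(new_groups) <- map$sample_id
  wells$group[is_sample] <- unname(new_groups[wells$sample_id[is_sample]])
  wells
}
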