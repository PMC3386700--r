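# Small cohorts keep the exhaustive subset search fast in unit tests:
# a k-vesicle panel has 2^k - 1 candidate subsets per repeat.

small_panel <- function(k = 4) default_panel()[seq_len(k), , drop = FALSE]

# cut-down three-group config; effect pattern mirrors the default cohort
small_config <- function(seed = 1, n_per_group = 12L, k = 4L, ...) {
  full <- default_cohort_config()
  synthetic_config(
    n_per_group = n_per_group,
    panel = small_panel(k),
    group_effect = full$group_effect[, seq_len(k), drop = FALSE],
    seed = seed, ...)
}

# deterministic generator: no noise, no plate distortion
noise_free_config <- function(group_effect, seed = 1, n_per_group = 4L,
                              k = ncol(group_effect), serum_sd = 0) {
  synthetic_config(
    n_per_group = n_per_group, panel = small_panel(k),
    group_effect = group_effect,
    em_c_sd = 0, em_r_sd = 0, serum_sd = serum_sd, replicate_sd = 0,
    plate_gain_sd = 0, plate_offset_sd = 0, seed = seed)
}

flat_effect <- function(level = 50, k = 4L,
                        groups = c("control", "stomach", "pancreas")) {
  matrix(level, nrow = length(groups), ncol = k,
         dimnames = list(groups, NULL))
}

# hand-built single plate: n_sera clinical sera (alternating groups),
# replicate_count wells each, plus color controls and optional standards
toy_plate <- function(n_sera = 6, replicate_count = 1, em_c = 100,
                      em_r = 1100, fcr = NULL, groups = c("control", "stomach"),
                      plate_id = "p1", vesicle_id = "V1", standards = character()) {
  if (is.null(fcr)) fcr <- rep(50, n_sera)
  sera <- sprintf("s%02d", seq_len(n_sera))
  grp <- rep_len(groups, n_sera)
  std_f <- if (length(standards)) {
    rep(seq(30, 70, length.out = length(standards)), each = replicate_count)
  } else {
    numeric(0)
  }
  ids <- c("", "", rep(sera, each = replicate_count),
           rep(standards, each = replicate_count))
  roles <- c("neg_control", "pos_control",
             rep("sample", n_sera * replicate_count),
             rep("standard", length(standards) * replicate_count))
  grps <- c("none", "none", rep(grp, each = replicate_count),
            rep("none", length(standards) * replicate_count))
  f <- c(0, 100, rep(fcr, each = replicate_count), std_f)
  data.frame(
    plate_id = plate_id, vesicle_id = vesicle_id,
    well = as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))[seq_along(ids)],
    sample_id = ids, role = roles, group = grps,
    emission = em_c + f / 100 * (em_r - em_c),
    stringsAsFactors = FALSE)
}
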