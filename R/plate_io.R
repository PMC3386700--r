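#' Detector-vesicle panel used by default
#'
#' The standard panel of ten lipid/PDA detector vesicles: each entry gives
#' the lipid composition co-polymerized with PDA, the lipid:PDA mole ratio,
#' and the buffer pH chosen to equilibrate intrinsic sensitivity.
#'
#' @return a data.frame with columns `vesicle_id`, `composition`,
#'   `mole_ratio`, `ph` (10 rows, ids `V1`..`V10`).
#' @seealso [read_panel()]
#' @export
#' @examples
#' default_panel()
default_panel <- function() {
  path <- system.file("extdata", "default_panel.csv", package = "reactomics",
                      mustWork = TRUE)
  read_panel(path)
}

#' Read a detector-panel description file
#'
#' @param path CSV with columns `vesicle_id,composition,mole_ratio,ph`.
#' @return validated panel data.frame.
#' @export
read_panel <- function(path) {
  check_that(file.exists(path), "panel file not found: %s", path)
  panel <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(vesicle_id = "character",
                                          composition = "character",
                                          mole_ratio = "character",
                                          ph = "numeric"))
  required <- c("vesicle_id", "composition", "mole_ratio", "ph")
  missing <- setdiff(required, names(panel))
  check_that(length(missing) == 0L,
             "panel file lacks required column(s): %s",
             paste(missing, collapse = ", "))
  check_that(!anyDuplicated(panel$vesicle_id),
             "panel vesicle_id values must be unique")
  panel
}

plate_columns <- c("plate_id", "vesicle_id", "well", "sample_id",
                   "role", "group", "emission")
plate_roles <- c("sample", "standard", "neg_control", "pos_control")

well_syntax_ok <- function(well) {
  m <- regmatches(well, regexec("^([A-H])([0-9]{1,2})$", well))
  vapply(m, function(g) {
    length(g) == 3L && as.integer(g[3]) >= 1L && as.integer(g[3]) <= 12L
  }, logical(1))
}

#' Validate well-level plate data
#'
#' Enforces the plate data model: one detector vesicle per plate, at least
#' one negative and one positive color-control well, every clinical serum
#' measured in exactly `replicate_count` wells, color controls carrying no
#' sample identity, a common standardization-serum set across plates, and
#' finite non-negative emissions.
#'
#' @param wells data.frame in the plate CSV layout (see [read_plates()]).
#' @param replicate_count wells per clinical serum per plate (default 3;
#'   set to 10 for repeatability assays).
#' @param groups optional character vector of allowed clinical group labels;
#'   by default any label is accepted (plus `"none"` for controls).
#' @return `wells`, invisibly, after validation.
#' @export
validate_plates <- function(wells, replicate_count = 3L, groups = NULL) {
  missing <- setdiff(plate_columns, names(wells))
  check_that(length(missing) == 0L,
             "plate data lacks required column(s): %s",
             paste(missing, collapse = ", "))
  check_that(nrow(wells) > 0L, "plate data has no rows")
  check_that(is.numeric(wells$emission), "column 'emission' must be numeric")
  bad <- which(!is.finite(wells$emission) | wells$emission < 0)
  check_that(length(bad) == 0L,
             "non-finite or negative emission at row(s): %s",
             paste(utils::head(bad, 5L), collapse = ", "))

  bad_role <- which(!wells$role %in% plate_roles)
  check_that(length(bad_role) == 0L,
             "unknown role token at row(s) %s (allowed: %s)",
             paste(utils::head(bad_role, 5L), collapse = ", "),
             paste(plate_roles, collapse = ", "))
  if (!is.null(groups)) {
    bad_grp <- which(!wells$group %in% c(groups, "none"))
    check_that(length(bad_grp) == 0L,
               "unknown group token at row(s): %s",
               paste(utils::head(bad_grp, 5L), collapse = ", "))
  }

  bad_well <- which(!well_syntax_ok(wells$well))
  check_that(length(bad_well) == 0L,
             "malformed well coordinate (expect A1-H12) at row(s): %s",
             paste(utils::head(bad_well, 5L), collapse = ", "))

  ctrl <- wells$role %in% c("neg_control", "pos_control")
  check_that(all(wells$sample_id[ctrl] == ""),
             "color-control wells must have empty sample_id")
  check_that(all(wells$group[ctrl] == "none"),
             "color-control wells must have group 'none'")
  check_that(all(wells$sample_id[!ctrl] != ""),
             "sample and standard wells must carry a sample_id")

  std_sets <- list()
  for (pid in unique(wells$plate_id)) {
    p <- wells[wells$plate_id == pid, , drop = FALSE]
    check_that(length(unique(p$vesicle_id)) == 1L,
               "plate '%s' mixes vesicle types: %s", pid,
               paste(unique(p$vesicle_id), collapse = ", "))
    check_that(any(p$role == "neg_control"),
               "plate '%s' has no neg_control well", pid)
    check_that(any(p$role == "pos_control"),
               "plate '%s' has no pos_control well", pid)
    n_rep <- table(p$sample_id[p$role == "sample"])
    off <- n_rep[n_rep != replicate_count]
    check_that(length(off) == 0L,
               "plate '%s': serum '%s' has %d well(s), expected %d",
               pid, names(off)[1] %||% "", off[1] %||% 0L,
               as.integer(replicate_count))
    std_sets[[pid]] <- sort(unique(p$sample_id[p$role == "standard"]))
  }
  if (length(std_sets) > 1L) {
    ref <- std_sets[[1]]
    same <- vapply(std_sets, identical, logical(1), y = ref)
    check_that(all(same),
               "standardization serum set differs between plates ('%s' vs '%s')",
               names(std_sets)[1], names(std_sets)[!same][1])
  }
  invisible(wells)
}

#' Read plate data from CSV
#'
#' The plate format is a plain comma-separated UTF-8 file with one header
#' row and columns exactly
#' `plate_id,vesicle_id,well,sample_id,role,group,emission`. `role` is one
#' of `sample`, `standard`, `neg_control`, `pos_control`; the empty string
#' in `sample_id` and the token `none` in `group` mark color-control wells.
#' `emission` is raw fluorescence (arbitrary units, 544/620 nm
#' excitation/emission context). Row order is preserved.
#'
#' @inheritParams validate_plates
#' @param path file to read.
#' @param panel optional panel data.frame; when given, every `vesicle_id`
#'   must belong to it.
#' @return validated data.frame of wells.
#' @export
read_plates <- function(path, replicate_count = 3L, panel = NULL,
                        groups = NULL) {
  check_that(file.exists(path), "plate file not found: %s", path)
  header <- tryCatch(
    names(utils::read.csv(path, nrows = 1, check.names = FALSE)),
    error = function(e) stop("malformed plate CSV: ", conditionMessage(e),
                             call. = FALSE))
  missing <- setdiff(plate_columns, header)
  check_that(length(missing) == 0L,
             "plate data lacks required column(s): %s",
             paste(missing, collapse = ", "))
  wells <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(plate_id = "character",
                                   vesicle_id = "character",
                                   well = "character",
                                   sample_id = "character",
                                   role = "character",
                                   group = "character",
                                   emission = "numeric")),
    error = function(e) stop("malformed plate CSV: ", conditionMessage(e),
                             call. = FALSE))
  wells$sample_id[is.na(wells$sample_id)] <- ""
  wells$group[is.na(wells$group) | wells$group == ""] <- "none"
  validate_plates(wells, replicate_count = replicate_count, groups = groups)
  if (!is.null(panel)) {
    unknown <- setdiff(unique(wells$vesicle_id), panel$vesicle_id)
    check_that(length(unknown) == 0L,
               "vesicle_id(s) not in panel: %s", paste(unknown, collapse = ", "))
  }
  wells
}

#' Write plate data to CSV
#'
#' Emissions are serialized with full double precision (`%.17g`) so that
#' `read_plates(write_plates(x))` reproduces values bit-exactly.
#'
#' @param wells validated plate data.frame.
#' @param path output file.
#' @param replicate_count passed to [validate_plates()].
#' @return `path`, invisibly.
#' @export
write_plates <- function(wells, path, replicate_count = 3L) {
  validate_plates(wells, replicate_count = replicate_count)
  out <- wells[, plate_columns]
  out$emission <- sprintf("%.17g", out$emission)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  check_that(ok, "cannot write plate file: %s", path)
  invisible(path)
}
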