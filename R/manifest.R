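#' Load and validate a cohort manifest
#'
#' The manifest drives every statistical design: one row per subject and
#' session, with group membership (`TBI` or `HC`), the age/sex covariates,
#' and, for injured subjects, the scan-interval variables. Healthy controls
#' are imaged once; TBI subjects at one or two sessions (subacute and
#' chronic).
#'
#' @param path Path to a tab-delimited file with columns `subject_id`,
#'   `group` (`TBI`/`HC`), `age` (years), `sex` (`F`/`M`), `session`
#'   (1 or 2), and optionally `days_post_injury`, `days_between_scans`,
#'   `has_mri`, `has_pet`.
#' @return A validated tibble, one row per subject-session.
#' @export
load_manifest <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_manifest(tbl)
}

#' Validate a manifest tibble
#'
#' @param tbl A data frame shaped as in [load_manifest()].
#' @return The validated tibble (invisibly identical content, ordered by
#'   subject and session).
#' @export
validate_manifest <- function(tbl) {
  req <- c("subject_id", "group", "age", "sex", "session")
  missing_cols <- setdiff(req, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(tbl$group %in% c("TBI", "HC"))) {
    bad <- setdiff(unique(tbl$group), c("TBI", "HC"))
    abort(paste0("unknown group label: ", paste(bad, collapse = ", ")))
  }
  if (!all(tbl$sex %in% c("F", "M"))) abort("sex must be F or M")
  if (!all(is.finite(tbl$age)) || any(tbl$age <= 0)) abort("age must be > 0")
  if (!all(tbl$session %in% c(1, 2))) abort("session must be 1 or 2")
  per <- dplyr::summarise(
    dplyr::group_by(tbl, .data$subject_id, .data$group),
    n_ses = dplyr::n(),
    dup = anyDuplicated(.data$session) > 0,
    .groups = "drop")
  if (any(per$dup)) {
    abort(paste0("duplicated session for subject ",
                 per$subject_id[which(per$dup)[1]]))
  }
  hc_multi <- per$group == "HC" & per$n_ses != 1
  if (any(hc_multi)) {
    abort(paste0("HC subjects must have exactly one session: ",
                 paste(per$subject_id[hc_multi], collapse = ", ")))
  }
  tbi_many <- per$group == "TBI" & per$n_ses > 2
  if (any(tbi_many)) {
    abort(paste0("TBI subjects may have at most two sessions: ",
                 paste(per$subject_id[tbi_many], collapse = ", ")))
  }
  multi_group <- dplyr::count(per, .data$subject_id)
  if (any(multi_group$n > 1)) abort("a subject appears in both groups")
  dplyr::arrange(tibble::as_tibble(tbl), .data$subject_id, .data$session)
}

#' Subjects with both longitudinal sessions
#'
#' @param manifest A validated manifest tibble.
#' @return Character vector of TBI subject ids having sessions 1 and 2.
#' @export
longitudinal_subjects <- function(manifest) {
  per <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(manifest, .data$group == "TBI"),
                    .data$subject_id),
    both = all(c(1, 2) %in% .data$session), .groups = "drop")
  per$subject_id[per$both]
}
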