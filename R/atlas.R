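#' Load and validate an 86-region atlas table
#'
#' The analyses in this package run on a fixed 86-region gray-matter
#' parcellation: 68 Desikan-Killiany cortical gyri plus 18 subcortical
#' regions. The atlas table fixes the canonical region ordering used by
#' every matrix and metric vector downstream, carries region volumes (used
#' to normalise streamline counts) and a functional-network label (used for
#' plotting and the cortex-only subsets).
#'
#' @param path Path to a tab-delimited file with columns `region_id`
#'   (integer, 0-based, contiguous), `name`, `hemisphere`
#'   (`left`/`right`/`midline`), `is_cortical` (logical), `volume`
#'   (mm^3, positive), and `network`.
#' @return A tibble with exactly 86 rows, ordered by `region_id`.
#' @examples
#' atlas <- default_atlas()
#' sum(atlas$is_cortical)
#' @export
load_atlas <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("region_id", "name", "hemisphere", "is_cortical", "volume", "network")
  missing_cols <- setdiff(req, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("atlas file is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tbl) != N_REGIONS) {
    abort(sprintf("expected 86 regions, got %d", nrow(tbl)))
  }
  tbl <- dplyr::arrange(tbl, .data$region_id)
  if (anyDuplicated(tbl$region_id) > 0) abort("duplicate region_id values")
  if (!identical(as.integer(tbl$region_id), 0:85)) {
    abort("region_id values must be contiguous integers 0..85")
  }
  if (!all(tbl$hemisphere %in% c("left", "right", "midline"))) {
    abort("hemisphere must be one of left/right/midline")
  }
  if (!is.logical(tbl$is_cortical)) abort("is_cortical must be logical")
  if (sum(tbl$is_cortical) != N_CORTICAL) {
    abort(sprintf("expected 68 cortical regions, got %d", sum(tbl$is_cortical)))
  }
  if (!all(is.finite(tbl$volume)) || any(tbl$volume <= 0)) {
    abort("region volumes must be positive")
  }
  tbl
}

#' Packaged default atlas
#'
#' The 86-region table shipped with the package. The 18 subcortical regions
#' follow the standard FreeSurfer aseg gray-matter set; volumes and network
#' labels are plausible synthetic values, and the file is user-replaceable
#' via [load_atlas()].
#'
#' @return A validated 86-row atlas tibble.
#' @export
default_atlas <- function() {
  load_atlas(system.file("extdata", "atlas_dk86.tsv", package = "tbifuse"))
}

#' Cortex-only region mask
#'
#' @param atlas An atlas tibble from [load_atlas()].
#' @return Logical vector of length 86 (in `region_id` order) with exactly
#'   68 `TRUE` entries.
#' @export
cortex_mask <- function(atlas) {
  atlas$is_cortical[order(atlas$region_id)]
}
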