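#' Read a connectivity matrix from a delimited text file
#'
#' Expects a whitespace/tab-delimited 86 x 86 numeric grid (no header).
#' Symmetry is checked on read; round-tripping through [write_matrix()]
#' preserves values to better than 1e-12.
#'
#' @param path File path.
#' @param kind `"FC"` or `"SC"`.
#' @return A [conn_matrix()].
#' @export
read_matrix <- function(path, kind = c("FC", "SC")) {
  kind <- match.arg(kind)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) abort("matrix file is not square")
  conn_matrix(m, kind = kind)
}

#' Write a connectivity matrix to a delimited text file
#'
#' @param m A [conn_matrix()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  if (!inherits(m, "conn_matrix")) abort("`m` must be a conn_matrix")
  txt <- apply(m$values, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(txt, path)
  invisible(path)
}

#' Read / write a TAC table
#'
#' TAC tables are tab-delimited with columns `frame_start_s`,
#' `frame_duration_s`, `pons` (reference region) and one activity column
#' per atlas region named `r0` .. `r85` in region order.
#'
#' @param path File path.
#' @return [read_tacs()] returns a [tac_set()].
#' @export
read_tacs <- function(path) {
  tbl <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  req <- c("frame_start_s", "frame_duration_s", "pons")
  if (!all(req %in% names(tbl))) {
    abort("TAC table needs columns frame_start_s, frame_duration_s, pons")
  }
  rcols <- paste0("r", 0:85)
  if (!all(rcols %in% names(tbl))) abort("TAC table needs columns r0..r85")
  tac_set(frame_start = tbl$frame_start_s,
          frame_duration = tbl$frame_duration_s,
          activity = t(as.matrix(tbl[, rcols])),
          reference_activity = tbl$pons)
}

#' @rdname read_tacs
#' @param tac A [tac_set()].
#' @export
write_tacs <- function(tac, path) {
  tbl <- data.frame(frame_start_s = tac$frame_start,
                    frame_duration_s = tac$frame_duration,
                    pons = tac$reference_activity,
                    t(tac$activity), check.names = FALSE)
  names(tbl)[-(1:3)] <- paste0("r", 0:85)
  utils::write.table(format(tbl, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a regional metric map table
#'
#' Long-format tab-delimited table with columns `metric`, `subject_id`,
#' `session`, `region_id`, `value`. fALFF values must lie in `[0, 1]`;
#' node strengths must be non-negative.
#'
#' @param path File path.
#' @return A tibble of per-region metric values.
#' @export
read_metric_map <- function(path) {
  tbl <- tibble::as_tibble(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE))
  validate_metric_map(tbl)
}

#' @rdname read_metric_map
#' @param map A metric-map tibble.
#' @export
write_metric_map <- function(map, path) {
  validate_metric_map(map)
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_metric_map <- function(tbl) {
  req <- c("metric", "subject_id", "session", "region_id", "value")
  if (!all(req %in% names(tbl))) {
    abort("metric map needs columns metric, subject_id, session, region_id, value")
  }
  known <- c("BPND", "fALFF", "FC_strength", "SC_strength")
  if (!all(tbl$metric %in% known)) {
    abort(paste0("unknown metric label; expected one of ",
                 paste(known, collapse = ", ")))
  }
  fa <- tbl$value[tbl$metric == "fALFF" & !is.na(tbl$value)]
  if (length(fa) && (any(fa < 0) || any(fa > 1))) {
    abort("fALFF values must lie in [0, 1]")
  }
  st <- tbl$value[tbl$metric %in% c("FC_strength", "SC_strength") & !is.na(tbl$value)]
  if (length(st) && any(st < 0)) abort("node strengths must be >= 0")
  tbl
}
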