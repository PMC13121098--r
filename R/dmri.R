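#' Structural connectivity from streamline-endpoint counts
#'
#' Normalises a symmetric streamline-endpoint count matrix by the total
#' volume of each region pair: `SC_ij = counts_ij / (vol_i + vol_j)`.
#' "Total volume" is interpreted as the sum of the two region volumes;
#' set `pair_volume = "product"` for the product convention instead.
#' The diagonal is carried through but ignored by all downstream strength
#' computations.
#'
#' @param counts Integer-valued symmetric 86 x 86 matrix of streamline
#'   endpoint counts (>= 0).
#' @param volumes Numeric vector of 86 region volumes (mm^3, > 0),
#'   in atlas region order.
#' @param pair_volume `"sum"` (default) or `"product"`.
#' @return A [conn_matrix()] of kind SC.
#' @export
sc_from_counts <- function(counts, volumes, pair_volume = c("sum", "product")) {
  pair_volume <- match.arg(pair_volume)
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("streamline counts must be >= 0")
  if (max(abs(counts - t(counts))) > 0) abort("count matrix must be symmetric")
  if (length(volumes) != nrow(counts)) {
    abort("one volume per region is required")
  }
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    abort("region volumes must be positive")
  }
  denom <- if (pair_volume == "sum") outer(volumes, volumes, `+`)
           else outer(volumes, volumes, `*`)
  conn_matrix(counts / denom, kind = "SC")
}

#' Control-based SC edge sparsification
#'
#' Mitigates false-positive connections: an edge is zeroed in every matrix
#' (controls and injured subjects, all sessions) if it is zero in at least
#' 50% of the control subjects, i.e. in `ceil(n_controls / 2)` or more of
#' them.
#'
#' @param matrices A list of [conn_matrix()] objects of kind SC (the whole
#'   dataset, all groups and sessions).
#' @param is_control Logical vector, one entry per matrix, marking the
#'   uninjured-control matrices used to define the retained-edge mask.
#' @return A list with `matrices` (the sparsified list, same order) and
#'   `edge_mask` (logical 86 x 86, `TRUE` = edge retained).
#' @export
control_sparsify <- function(matrices, is_control) {
  if (length(matrices) != length(is_control)) {
    abort("one is_control flag per matrix is required")
  }
  if (!any(is_control)) abort("at least one control matrix is required")
  ok <- vapply(matrices, function(m) inherits(m, "conn_matrix") && m$kind == "SC",
               logical(1))
  if (!all(ok)) abort("all matrices must be conn_matrix objects of kind SC")
  ctrl <- matrices[is_control]
  n_ctrl <- length(ctrl)
  zero_count <- Reduce(`+`, lapply(ctrl, function(m) (m$values == 0) * 1L))
  drop <- zero_count >= ceiling(0.5 * n_ctrl)
  diag(drop) <- FALSE                      # diagonal not an edge
  out <- lapply(matrices, function(m) {
    v <- m$values
    v[drop] <- 0
    conn_matrix(v, kind = "SC")
  })
  list(matrices = out, edge_mask = !drop)
}

#' SC node strength
#'
#' Per-region sum of each row of the SC matrix, excluding the diagonal.
#'
#' @param sc A [conn_matrix()] of kind SC.
#' @return Numeric vector of length 86.
#' @export
sc_node_strength <- function(sc) {
  if (!inherits(sc, "conn_matrix") || sc$kind != "SC") {
    abort("sc_node_strength requires a conn_matrix of kind SC")
  }
  v <- sc$values
  diag(v) <- 0
  rowSums(v)
}
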