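#' Regional BOLD time-series container
#'
#' Holds one run of regional mean BOLD series on the 86-region
#' parcellation, together with the sampling interval, the phase-encoding
#' run label, and the outlier censor mask used by denoising, connectivity
#' and fALFF computations.
#'
#' @param data Numeric matrix, 86 regions x T timepoints.
#' @param dt Sampling interval in seconds (TR); the study acquisition is
#'   420 volumes at TR = 0.8 s per run.
#' @param run Run label, `"AP"` or `"PA"`.
#' @param censor_mask Logical vector of length T; `TRUE` marks an outlier
#'   timepoint. Defaults to all `FALSE`.
#' @return An object of class `regional_ts`.
#' @export
regional_ts <- function(data, dt, run = "AP", censor_mask = NULL) {
  data <- as.matrix(data)
  if (nrow(data) != N_REGIONS) {
    abort(sprintf("expected 86 region rows, got %d", nrow(data)))
  }
  if (ncol(data) < 2) abort("time series must have at least 2 timepoints")
  stop_if_not_scalar_number(dt, "dt")
  if (dt <= 0) abort("dt must be > 0")
  if (!run %in% c("AP", "PA")) abort("run must be AP or PA")
  if (is.null(censor_mask)) censor_mask <- rep(FALSE, ncol(data))
  if (!is.logical(censor_mask) || length(censor_mask) != ncol(data)) {
    abort("censor_mask must be logical with one entry per timepoint")
  }
  structure(list(data = data, dt = dt, run = run,
                 censor_mask = censor_mask),
            class = "regional_ts")
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf("<regional_ts> %d regions x %d timepoints, dt = %g s, run %s, %d censored\n",
              nrow(x$data), ncol(x$data), x$dt, x$run, sum(x$censor_mask)))
  invisible(x)
}

#' PET time-activity curve set
#'
#' Per-region radiotracer activity over a dynamic frame schedule, plus the
#' designated reference-region (pons) curve used by reference-region Logan
#' analysis. Frames must be contiguous and non-overlapping.
#'
#' @param frame_start Numeric vector of frame start times (seconds).
#' @param frame_duration Numeric vector of frame durations (seconds, > 0).
#' @param activity Numeric matrix, 86 regions x F frames, activity in any
#'   consistent concentration unit (e.g. kBq/mL).
#' @param reference_activity Numeric vector of length F: the reference
#'   (pons) curve.
#' @return An object of class `tac_set`.
#' @export
tac_set <- function(frame_start, frame_duration, activity, reference_activity) {
  activity <- as.matrix(activity)
  f <- length(frame_start)
  if (f < 3) abort("need at least 3 frames")
  if (length(frame_duration) != f) abort("frame_start/frame_duration length mismatch")
  if (any(frame_duration <= 0)) abort("frame durations must be > 0")
  gaps <- frame_start[-1] - (frame_start[-f] + frame_duration[-f])
  if (any(abs(gaps) > 1e-6)) {
    abort("frames must be contiguous and non-overlapping")
  }
  if (nrow(activity) != N_REGIONS) {
    abort(sprintf("expected 86 region rows, got %d", nrow(activity)))
  }
  if (ncol(activity) != f) abort("activity must have one column per frame")
  if (length(reference_activity) != f) {
    abort("reference_activity must have one value per frame")
  }
  dimnames(activity) <- NULL
  structure(list(frame_start = as.numeric(frame_start),
                 frame_duration = as.numeric(frame_duration),
                 activity = activity,
                 reference_activity = as.numeric(reference_activity)),
            class = "tac_set")
}

#' @export
print.tac_set <- function(x, ...) {
  cat(sprintf("<tac_set> %d regions x %d frames, %g s total\n",
              nrow(x$activity), length(x$frame_start), sum(x$frame_duration)))
  invisible(x)
}

#' Frame midpoints of a TAC schedule
#' @param tac A `tac_set`.
#' @return Numeric vector of frame midpoint times (seconds).
#' @export
frame_midpoints <- function(tac) tac$frame_start + tac$frame_duration / 2

#' Connectivity matrix container
#'
#' A symmetric 86 x 86 region-by-region matrix: Pearson correlations for
#' functional connectivity (`kind = "FC"`) or volume-normalised streamline
#' counts for structural connectivity (`kind = "SC"`). The diagonal is
#' stored but ignored by all node-strength computations.
#'
#' @param values Numeric symmetric 86 x 86 matrix.
#' @param kind `"FC"` or `"SC"`.
#' @param tol Symmetry tolerance (absolute), default `1e-10`.
#' @return An object of class `conn_matrix`.
#' @export
conn_matrix <- function(values, kind = c("FC", "SC"), tol = 1e-10) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort("connectivity matrix must be square")
  if (nrow(values) != N_REGIONS) {
    abort(sprintf("expected an 86 x 86 matrix, got %d x %d",
                  nrow(values), ncol(values)))
  }
  if (max(abs(values - t(values))) > tol) {
    abort("connectivity matrix is asymmetric beyond tolerance")
  }
  off <- values[upper.tri(values)]
  if (kind == "SC" && any(off < 0)) abort("SC values must be >= 0")
  if (kind == "FC" && any(off < -1 - 1e-12 | off > 1 + 1e-12)) {
    abort("FC values must lie in [-1, 1]")
  }
  structure(list(values = values, kind = kind), class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> kind %s, 86 x 86\n", x$kind))
  invisible(x)
}
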