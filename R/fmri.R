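#' Detect outlier timepoints from motion and global signal
#'
#' Flags a timepoint when the framewise motion derivative (summed absolute
#' change across the six rigid-body parameters, rotations converted to mm
#' on a 50 mm sphere) exceeds `motion_thresh`, or when the global signal
#' (mean over regions) deviates from its mean by more than `global_thresh`
#' standard deviations. The global-signal SD is computed on the raw
#' regional-mean series, before any nuisance regression. The first
#' timepoint's derivative is defined as 0.
#'
#' @param ts A [regional_ts()].
#' @param motion6 Numeric T x 6 matrix: translations (mm) in columns 1-3,
#'   rotations (radians) in columns 4-6.
#' @param motion_thresh Framewise displacement threshold in mm (default 0.9).
#' @param global_thresh Global-signal threshold in SD units (default 5).
#' @param radius Sphere radius (mm) for the rotation-to-mm conversion.
#' @return Logical vector of length T; `TRUE` marks an outlier.
#' @export
detect_outliers <- function(ts, motion6, motion_thresh = 0.9,
                            global_thresh = 5, radius = 50) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6) abort("motion6 must have 6 columns")
  if (nrow(motion6) != ncol(ts$data)) {
    abort("motion table and time series have different lengths")
  }
  scaled <- motion6
  scaled[, 4:6] <- scaled[, 4:6] * radius
  fd <- c(0, rowSums(abs(diff(scaled))))
  g <- colMeans(ts$data)
  gs <- sd(g)
  gflag <- if (gs > 0) abs(g - mean(g)) > global_thresh * gs else rep(FALSE, length(g))
  fd > motion_thresh | gflag
}

#' Expand six motion parameters to the 24-regressor set
#'
#' Columns are, for each parameter p: p, p^2, the backward difference
#' delta-p (0 at the first timepoint), and (delta-p)^2.
#'
#' @param motion6 Numeric T x 6 motion-parameter matrix.
#' @return Numeric T x 24 matrix.
#' @export
expand_motion24 <- function(motion6) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6) abort("motion6 must have 6 columns")
  d <- rbind(0, diff(motion6))
  out <- cbind(motion6, motion6^2, d, d^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("p", 1:6, "_sq"),
                     paste0("dp", 1:6), paste0("dp", 1:6, "_sq"))
  out
}

#' aCompCor nuisance eigenvectors
#'
#' Top-k left singular vectors of the column-demeaned white-matter/CSF
#' noise-compartment time-series matrix, ordered by singular value, each
#' unit-norm with a deterministic sign convention (largest-magnitude
#' element positive).
#'
#' @param noise_ts Numeric T x V matrix of noise-compartment series.
#' @param k Number of components (default 10).
#' @return Numeric T x k matrix of temporal components.
#' @export
compcor_eigenvectors <- function(noise_ts, k = 10) {
  x <- as.matrix(noise_ts)
  if (ncol(x) < k) {
    abort(sprintf("need at least %d noise series, got %d", k, ncol(x)))
  }
  x <- sweep(x, 2, colMeans(x))
  u <- svd(x, nu = k, nv = 0)$u
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  u
}

#' Discrete cosine high-pass basis
#'
#' DCT-II basis functions with frequency below the cutoff, excluding the
#' constant term (handled by the regression intercept). Regressing these
#' out implements a high-pass filter at the cutoff. The basis size is
#' K = #\{k >= 1 : k / (2 T dt) < cutoff\}.
#'
#' @param n_time Number of timepoints T.
#' @param dt Sampling interval (seconds).
#' @param cutoff High-pass cutoff in Hz (default 0.008).
#' @return Numeric T x K matrix (K may be 0).
#' @export
dct_basis <- function(n_time, dt, cutoff = 0.008) {
  kmax <- floor(2 * n_time * dt * cutoff)
  if (2 * n_time * dt * cutoff == kmax) kmax <- kmax - 1L  # strict inequality
  kmax <- max(0L, as.integer(kmax))
  t_idx <- seq_len(n_time) - 0.5
  b <- vapply(seq_len(kmax),
              function(k) cos(pi * k * t_idx / n_time), numeric(n_time))
  matrix(b, nrow = n_time)
}

#' Assemble the nuisance regressor set
#'
#' Convenience constructor for the standard denoising design: 24 motion
#' regressors, 10 aCompCor eigenvectors, and the DCT high-pass basis.
#'
#' @param motion6 T x 6 motion-parameter matrix.
#' @param noise_ts T x V noise-compartment matrix.
#' @param dt Sampling interval (seconds).
#' @param n_compcor Number of aCompCor components (default 10).
#' @param hp_cutoff High-pass cutoff in Hz (default 0.008).
#' @return A list with elements `motion24`, `compcor`, `dct`.
#' @export
nuisance_set <- function(motion6, noise_ts, dt, n_compcor = 10,
                         hp_cutoff = 0.008) {
  m24 <- expand_motion24(motion6)
  cc <- compcor_eigenvectors(noise_ts, k = n_compcor)
  if (nrow(cc) != nrow(m24)) abort("motion and noise tables differ in length")
  dct <- dct_basis(nrow(m24), dt, hp_cutoff)
  if (any(!is.finite(m24)) || any(!is.finite(cc))) {
    abort("nuisance regressors contain non-finite values")
  }
  list(motion24 = m24, compcor = cc, dct = dct)
}

#' Nuisance regression of regional BOLD series
#'
#' Regresses the nuisance set (plus an intercept) out of every regional
#' series. Regression coefficients are estimated on non-censored
#' timepoints only; residuals are returned at all timepoints, with the
#' censored timepoints re-flagged in the returned censor mask so that
#' downstream computations continue to exclude them.
#'
#' @param ts A [regional_ts()].
#' @param nuisance A list as returned by [nuisance_set()].
#' @param censor Optional logical vector of outliers to censor, combined
#'   (OR) with `ts$censor_mask`.
#' @return A [regional_ts()] of residuals.
#' @export
denoise <- function(ts, nuisance, censor = NULL) {
  n_t <- ncol(ts$data)
  mask <- ts$censor_mask
  if (!is.null(censor)) {
    if (length(censor) != n_t) abort("censor length mismatch")
    mask <- mask | censor
  }
  x <- cbind(1, nuisance$motion24, nuisance$compcor, nuisance$dct)
  if (nrow(x) != n_t) abort("nuisance regressors and series differ in length")
  keep <- !mask
  if (sum(keep) <= ncol(x)) {
    abort("fewer non-censored timepoints than regressors")
  }
  qr_fit <- qr(x[keep, , drop = FALSE])
  beta <- qr.coef(qr_fit, t(ts$data[, keep, drop = FALSE]))
  beta[is.na(beta)] <- 0
  resid <- ts$data - t(x %*% beta)
  regional_ts(resid, dt = ts$dt, run = ts$run, censor_mask = mask)
}

#' Functional connectivity matrix from two runs
#'
#' Pearson correlation between regional series over the non-censored
#' timepoints of each run, then the element-wise mean of the two per-run
#' matrices (raw-r averaging; Fisher-z averaging available via
#' `average = "fisher_z"`). The diagonal is set to 1.
#'
#' @param ts_ap,ts_pa Denoised [regional_ts()] objects for the AP and PA
#'   runs.
#' @param average `"raw"` (default) or `"fisher_z"`.
#' @return A [conn_matrix()] of kind FC.
#' @export
fc_matrix <- function(ts_ap, ts_pa, average = c("raw", "fisher_z")) {
  average <- match.arg(average)
  run_cor <- function(ts) {
    keep <- !ts$censor_mask
    if (sum(keep) < 3) abort("fewer than 3 usable timepoints in a run")
    cor(t(ts$data[, keep, drop = FALSE]))
  }
  c1 <- run_cor(ts_ap)
  c2 <- run_cor(ts_pa)
  if (average == "raw") {
    m <- (c1 + c2) / 2
  } else {
    z <- (atanh(pmin(pmax(c1, -1 + 1e-15), 1 - 1e-15)) +
          atanh(pmin(pmax(c2, -1 + 1e-15), 1 - 1e-15))) / 2
    m <- tanh(z)
  }
  diag(m) <- 1
  m <- (m + t(m)) / 2
  conn_matrix(m, kind = "FC")
}

#' FC node strength (positive-sum)
#'
#' Per-region sum of the positive off-diagonal elements of the FC matrix;
#' negative correlations and the diagonal are excluded.
#'
#' @param fc A [conn_matrix()] of kind FC.
#' @return Numeric vector of length 86.
#' @export
fc_node_strength <- function(fc) {
  if (!inherits(fc, "conn_matrix") || fc$kind != "FC") {
    abort("fc_node_strength requires a conn_matrix of kind FC")
  }
  v <- fc$values
  diag(v) <- 0
  rowSums(pmax(v, 0))
}

#' Fractional amplitude of low-frequency fluctuations
#'
#' For each regional series (non-censored timepoints, demeaned), computes
#' the amplitude spectrum |FFT| and returns the ratio of summed amplitudes
#' in the low-frequency band to those in the full band. Band membership is
#' half-open, `[f_low, f_high)`, on the discrete frequency grid; the DC
#' bin is always excluded. The result lies in `[0, 1]` and is invariant to
#' positive rescaling of the series.
#'
#' @param ts A [regional_ts()].
#' @param low_band Numeric length-2: low band in Hz (default 0.01-0.09).
#' @param full_band Numeric length-2: full band in Hz (default
#'   0.008-0.625; the upper edge may not exceed the Nyquist frequency).
#' @return Numeric vector of length 86.
#' @export
falff <- function(ts, low_band = c(0.01, 0.09), full_band = c(0.008, 0.625)) {
  nyq <- 1 / (2 * ts$dt)
  if (full_band[2] > nyq + 1e-12) {
    abort(sprintf("full band upper edge %g Hz exceeds Nyquist %g Hz",
                  full_band[2], nyq))
  }
  if (low_band[1] >= low_band[2] || full_band[1] >= full_band[2]) {
    abort("band edges must be increasing")
  }
  x <- ts$data[, !ts$censor_mask, drop = FALSE]
  n <- ncol(x)
  if (n < 4) abort("too few usable timepoints for a spectrum")
  x <- sweep(x, 1, rowMeans(x))
  amp <- Mod(mvfft(t(x)))          # n x 86
  freq <- (seq_len(n) - 1) / (n * ts$dt)
  half <- freq <= nyq + 1e-12 & freq > 0   # positive frequencies, DC excluded
  in_low <- half & freq >= low_band[1] & freq < low_band[2]
  in_full <- half & freq >= full_band[1] & freq < full_band[2]
  if (!any(in_low) || !any(in_full)) {
    abort("a frequency band is empty after discretisation")
  }
  num <- colSums(amp[in_low, , drop = FALSE])
  den <- colSums(amp[in_full, , drop = FALSE])
  out <- ifelse(den > 0, num / den, NA_real_)
  pmin(pmax(out, 0), 1)
}

#' Voxel-level fALFF averaged within regions
#'
#' When voxel-level series are available, fALFF is computed per voxel and
#' then averaged within each region (the voxel-first convention);
#' [falff()] on regional mean series is the default path when they are
#' not.
#'
#' @param voxel_data Numeric V x T matrix of voxel series.
#' @param dt Sampling interval (seconds).
#' @param region_of Integer vector of length V: 0-based region id of each
#'   voxel.
#' @param censor_mask Optional logical vector of length T.
#' @inheritParams falff
#' @return Numeric vector of length 86 (NA for regions with no voxels).
#' @export
falff_voxels <- function(voxel_data, dt, region_of,
                         low_band = c(0.01, 0.09),
                         full_band = c(0.008, 0.625),
                         censor_mask = NULL) {
  voxel_data <- as.matrix(voxel_data)
  if (length(region_of) != nrow(voxel_data)) {
    abort("one region id per voxel row is required")
  }
  if (any(region_of < 0 | region_of > 85)) abort("region ids must be 0..85")
  n_t <- ncol(voxel_data)
  if (is.null(censor_mask)) censor_mask <- rep(FALSE, n_t)
  x <- voxel_data[, !censor_mask, drop = FALSE]
  n <- ncol(x)
  nyq <- 1 / (2 * dt)
  if (full_band[2] > nyq + 1e-12) {
    abort(sprintf("full band upper edge %g Hz exceeds Nyquist %g Hz",
                  full_band[2], nyq))
  }
  x <- sweep(x, 1, rowMeans(x))
  amp <- Mod(mvfft(t(x)))
  freq <- (seq_len(n) - 1) / (n * dt)
  half <- freq <= nyq + 1e-12 & freq > 0
  in_low <- half & freq >= low_band[1] & freq < low_band[2]
  in_full <- half & freq >= full_band[1] & freq < full_band[2]
  if (!any(in_low) || !any(in_full)) {
    abort("a frequency band is empty after discretisation")
  }
  den <- colSums(amp[in_full, , drop = FALSE])
  fv <- ifelse(den > 0, colSums(amp[in_low, , drop = FALSE]) / den, NA_real_)
  out <- rep(NA_real_, N_REGIONS)
  agg <- tapply(fv, factor(region_of, levels = 0:85), mean, na.rm = TRUE)
  out[] <- as.numeric(agg)
  pmin(pmax(out, 0), 1)
}

#' Run-averaged regional fALFF
#'
#' [falff()] applied to each run separately, then averaged across runs,
#' mirroring the run-averaging of the FC matrices. Set
#' `combine = "concatenate"` to compute a single spectrum on the
#' concatenated non-censored portions instead.
#'
#' @param ts_ap,ts_pa [regional_ts()] objects for the two runs.
#' @param combine `"average"` (default) or `"concatenate"`.
#' @inheritParams falff
#' @return Numeric vector of length 86.
#' @export
falff_runs <- function(ts_ap, ts_pa, low_band = c(0.01, 0.09),
                       full_band = c(0.008, 0.625),
                       combine = c("average", "concatenate")) {
  combine <- match.arg(combine)
  if (combine == "average") {
    (falff(ts_ap, low_band, full_band) + falff(ts_pa, low_band, full_band)) / 2
  } else {
    if (abs(ts_ap$dt - ts_pa$dt) > 1e-12) abort("runs differ in dt")
    joined <- regional_ts(
      cbind(ts_ap$data[, !ts_ap$censor_mask, drop = FALSE],
            ts_pa$data[, !ts_pa$censor_mask, drop = FALSE]),
      dt = ts_ap$dt, run = ts_ap$run)
    falff(joined, low_band, full_band)
  }
}
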