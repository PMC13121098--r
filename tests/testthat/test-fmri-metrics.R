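make_ts <- function(data, dt = 0.8, censor = NULL) {
  regional_ts(data, dt = dt, censor_mask = censor)
}

test_that("outlier detection applies both motion and global-signal criteria", {
  n_t <- 200
  set.seed(1)
  quiet <- matrix(rnorm(86 * n_t, 100, 1), 86)
  still <- matrix(0, n_t, 6)
  expect_false(any(detect_outliers(make_ts(quiet), still)))

  jump <- still
  jump[100, 1] <- 1.2                 # 1.2 mm translation step
  flags <- detect_outliers(make_ts(quiet), jump)
  expect_true(flags[100])
  # the return to baseline at t=101 is itself a >0.9 mm derivative
  expect_true(flags[101])
  expect_equal(sum(flags), 2)
})

test_that("outlier flags match a brute-force recomputation of both rules", {
  n_t <- 150
  set.seed(7)
  dat <- matrix(rnorm(86 * n_t, 50, 2), 86)
  dat[, 40] <- dat[, 40] + 60          # global spike
  motion <- matrix(rnorm(n_t * 6, 0, 0.15), n_t)
  motion[, 4:6] <- motion[, 4:6] / 50
  flags <- detect_outliers(make_ts(dat), motion)

  # independent loop-based oracle
  scaled <- motion
  scaled[, 4:6] <- scaled[, 4:6] * 50
  fd <- numeric(n_t)
  for (t in 2:n_t) fd[t] <- sum(abs(scaled[t, ] - scaled[t - 1, ]))
  g <- numeric(n_t)
  for (t in seq_len(n_t)) g[t] <- mean(dat[, t])
  oracle <- fd > 0.9 | abs(g - mean(g)) > 5 * sd(g)
  expect_identical(flags, oracle)
  expect_true(flags[40])
})

test_that("24-parameter motion expansion follows the quadratic/derivative scheme", {
  n_t <- 50
  const <- matrix(rep(c(1, -2, 0.5, 0.1, 0, 0.2), each = n_t), n_t)
  m24 <- expand_motion24(const)
  expect_equal(dim(m24), c(n_t, 24))
  expect_true(all(m24[, 13:24] == 0))          # derivatives of constants
  expect_equal(m24[, 7], rep(1, n_t))          # squares

  ramp <- matrix(seq_len(n_t), n_t, 6)
  m24r <- expand_motion24(ramp)
  expect_equal(m24r[-1, 13], rep(1, n_t - 1))  # d(ramp) constant

  set.seed(2)
  x <- matrix(rnorm(n_t * 6), n_t)
  m24x <- expand_motion24(x)
  d <- rbind(0, x[-1, ] - x[-n_t, ])
  expect_equal(unname(m24x), unname(cbind(x, x^2, d, d^2)))
})

test_that("aCompCor components match an independent covariance eigendecomposition", {
  n_t <- 120
  set.seed(5)
  x <- matrix(rnorm(n_t * 40), n_t)
  u <- compcor_eigenvectors(x, k = 10)
  expect_equal(dim(u), c(n_t, 10))
  expect_equal(colSums(u^2), rep(1, 10), tolerance = 1e-12)

  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(tcrossprod(xc), symmetric = TRUE)$vectors[, 1:10]
  for (j in 1:10) {
    expect_equal(abs(sum(u[, j] * ev[, j])), 1, tolerance = 1e-8)
  }

  # rank-1 input: first component carries all variance
  r1 <- outer(sin(seq_len(n_t) / 5), rnorm(40))
  u1 <- compcor_eigenvectors(r1 + matrix(rnorm(n_t * 40, 0, 1e-10), n_t))
  xc1 <- sweep(r1, 2, colMeans(r1))
  expect_gt(abs(cor(u1[, 1], xc1[, 1])), 0.999)
  expect_error(compcor_eigenvectors(x[, 1:5], k = 10), "at least")
})

test_that("DCT basis size matches the cutoff rule", {
  # K = #{k >= 1 : k / (2 T dt) < 0.008}
  expect_equal(ncol(dct_basis(420, 0.8)), 5)   # 2*420*0.8*0.008 = 5.376
  expect_equal(ncol(dct_basis(840, 0.8)), 10)
  b <- dct_basis(420, 0.8)
  # slowest component is monotone over the run (half a cosine cycle)
  expect_true(all(diff(b[, 1]) < 0))
})

test_that("denoising removes nuisance signal and honours the censor mask", {
  n_t <- 300
  set.seed(11)
  motion <- matrix(rnorm(n_t * 6, 0, 0.01), n_t)
  noise <- matrix(rnorm(n_t * 30), n_t)
  nuis <- nuisance_set(motion, noise, dt = 0.8)

  # a series equal to a nuisance column is annihilated
  sig <- matrix(rep(nuis$compcor[, 1], 86), 86, byrow = TRUE)
  res <- denoise(make_ts(sig), nuis)
  expect_lt(sqrt(sum(res$data[1, ]^2)) / sqrt(sum(sig[1, ]^2)), 1e-8)

  # residuals match an explicit normal-equations solve on the censored design
  dat <- matrix(rnorm(86 * n_t), 86)
  cens <- rep(FALSE, n_t)
  cens[c(10, 50, 200)] <- TRUE
  res2 <- denoise(make_ts(dat), nuis, censor = cens)
  x <- cbind(1, nuis$motion24, nuis$compcor, nuis$dct)
  xk <- x[!cens, ]
  beta <- solve(t(xk) %*% xk, t(xk) %*% t(dat[, !cens]))
  oracle <- dat - t(x %*% beta)
  expect_lt(max(abs(res2$data - oracle)), 1e-8)
  expect_identical(res2$censor_mask, cens)

  # censored timepoints never influence the fit
  dat_mod <- dat
  dat_mod[, cens] <- 1e6
  res3 <- denoise(make_ts(dat_mod), nuis, censor = cens)
  expect_lt(max(abs(res3$data[, !cens] - res2$data[, !cens])), 1e-6)

  # idempotency
  res4 <- denoise(res2, nuis)
  expect_lt(max(abs(res4$data - res2$data)) /
              max(abs(res2$data)), 1e-10)

  expect_error(denoise(make_ts(dat), nuis, censor = rep(TRUE, n_t)),
               "fewer non-censored")
})

test_that("FC matrix averages per-run correlations over usable timepoints", {
  n_t <- 400
  set.seed(21)
  base <- matrix(rnorm(86 * n_t), 86)
  dup <- base
  dup[2, ] <- base[1, ]                 # region 1 copied into region 2
  ts1 <- make_ts(dup)
  ts2 <- make_ts(dup + matrix(rnorm(86 * n_t, 0, 1e-8), 86))
  fc <- fc_matrix(ts1, ts2)
  expect_equal(fc$values[1, 2], 1, tolerance = 1e-6)
  expect_equal(diag(fc$values), rep(1, 86))

  # independent white noise: off-diagonals near zero at T = 2 x 400
  tsa <- make_ts(matrix(rnorm(86 * n_t), 86))
  tsb <- make_ts(matrix(rnorm(86 * n_t), 86))
  fc0 <- fc_matrix(tsa, tsb)
  off <- fc0$values[upper.tri(fc0$values)]
  # null sd is 1/sqrt(2 * (T - 2)); the max over 3655 pairs stays within
  # ~4.5 null SDs and the mean is centred on zero
  expect_lt(max(abs(off)), 4.5 / sqrt(2 * (n_t - 2)))
  expect_lt(abs(mean(off)), 0.01)

  # run averaging is the arithmetic mean of per-run correlations
  c1 <- cor(t(tsa$data))
  c2 <- cor(t(tsb$data))
  manual <- (c1 + c2) / 2
  diag(manual) <- 1
  expect_equal(fc0$values, manual, tolerance = 1e-12)

  short <- make_ts(matrix(rnorm(86 * 5), 86),
                   censor = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_error(fc_matrix(short, short), "fewer than 3")
})

test_that("FC node strength sums positive off-diagonal entries only", {
  expect_equal(fc_node_strength(conn_matrix(diag(86), "FC")), rep(0, 86))

  vals <- matrix(0, 86, 86)
  vals[1, 2] <- vals[2, 1] <- 0.5
  vals[1, 3] <- vals[3, 1] <- -0.2
  vals[1, 4] <- vals[4, 1] <- 0.3
  diag(vals) <- 1
  s <- fc_node_strength(conn_matrix(vals, "FC"))
  expect_equal(s[1], 0.8)

  fcv <- random_fc_values(seed = 9)
  s2 <- fc_node_strength(conn_matrix(fcv, "FC"))
  oracle <- numeric(86)
  for (i in 1:86) {
    for (j in 1:86) if (j != i && fcv[i, j] > 0) oracle[i] <- oracle[i] + fcv[i, j]
  }
  expect_equal(s2, oracle, tolerance = 1e-12)
  expect_true(all(s2 >= 0 & s2 <= 85))
  expect_error(fc_node_strength(conn_matrix(abs(fcv) / 2, "SC")), "kind FC")
})

test_that("fALFF separates in-band from out-of-band power", {
  n_t <- 420
  dt <- 0.8
  tt <- (0:(n_t - 1)) * dt
  f_on <- 17 / (n_t * dt)               # on-grid, inside 0.01-0.09 Hz
  sine_in <- matrix(rep(sin(2 * pi * f_on * tt), 86), 86, byrow = TRUE)
  expect_true(all(falff(make_ts(sine_in)) >= 0.99))

  sine_out <- matrix(rep(sin(2 * pi * 0.4 * tt), 86), 86, byrow = TRUE)
  expect_true(all(falff(make_ts(sine_out)) <= 0.01))

  # scale invariance and range
  set.seed(3)
  x <- matrix(rnorm(86 * n_t), 86)
  f1 <- falff(make_ts(x))
  f2 <- falff(make_ts(x * 37.5))
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_true(all(f1 >= 0 & f1 <= 1))

  expect_error(falff(make_ts(x), full_band = c(0.008, 0.7)), "Nyquist")
  expect_error(falff(make_ts(x), low_band = c(0.05, 0.0500001)), "empty")
})

test_that("white-noise fALFF matches the spectral bin-count ratio", {
  n_t <- 840
  dt <- 0.8
  freq <- (seq_len(n_t) - 1) / (n_t * dt)
  half <- freq > 0 & freq <= 1 / (2 * dt) + 1e-12
  n_low <- sum(half & freq >= 0.01 & freq < 0.09)
  n_full <- sum(half & freq >= 0.008 & freq < 0.625)
  expected <- n_low / n_full
  set.seed(8)
  vals <- replicate(20, mean(falff(make_ts(matrix(rnorm(86 * n_t), 86), dt))))
  mc_se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * mc_se + 0.002)
})

test_that("voxel-level fALFF averages per-voxel ratios within regions", {
  n_t <- 400
  dt <- 0.8
  set.seed(19)
  # two voxels per region; region k's voxels share its regional series
  reg <- rep(0:85, each = 2)
  base <- matrix(rnorm(86 * n_t), 86)
  vox <- base[reg + 1, ]
  fv <- falff_voxels(vox, dt, reg)
  fr <- falff(regional_ts(base, dt))
  expect_equal(fv, fr, tolerance = 1e-12)

  # with heterogeneous voxels the result is the mean of per-voxel fALFF
  vox2 <- matrix(rnorm(4 * n_t), 4)
  reg2 <- c(0L, 0L, 1L, 1L)
  fv2 <- falff_voxels(vox2, dt, reg2)
  one <- function(v) falff(regional_ts(matrix(rep(v, 86), 86, byrow = TRUE), dt))[1]
  expect_equal(fv2[1], (one(vox2[1, ]) + one(vox2[2, ])) / 2,
               tolerance = 1e-10)
  expect_true(all(is.na(fv2[3:86])))
})

test_that("fALFF and FC ignore censored timepoints entirely", {
  n_t <- 300
  set.seed(14)
  dat <- matrix(rnorm(86 * n_t), 86)
  cens <- rep(FALSE, n_t)
  cens[sample(n_t, 30)] <- TRUE
  ts_a <- make_ts(dat, censor = cens)
  dat_mod <- dat
  dat_mod[, cens] <- 1e9
  ts_b <- make_ts(dat_mod, censor = cens)
  expect_equal(falff(ts_a), falff(ts_b), tolerance = 1e-12)
  fc_a <- fc_matrix(ts_a, ts_a)
  fc_b <- fc_matrix(ts_b, ts_b)
  expect_equal(fc_a$values, fc_b$values, tolerance = 1e-12)
})
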