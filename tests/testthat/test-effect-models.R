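# Build a metric tibble for given subjects at one session per subject
# (TBI at `session`, HC at 1), from a named list subject -> length-86 values.
metrics_from_values <- function(values_by_subject, session_by_subject,
                                metric = "fALFF") {
  purrr::imap_dfr(values_by_subject, function(v, sid) {
    tibble::tibble(metric = metric, subject_id = sid,
                   session = session_by_subject[[sid]],
                   region_id = 0:85, value = v)
  })
}

test_that("ANCOVA group t is zero when groups are identical and noiseless", {
  man <- toy_manifest(n_tbi = 5, n_hc = 5)
  subs <- unique(man$subject_id)
  vals <- lapply(setNames(subs, subs), function(s) rep(seq(0, 8.5, 0.1), 1))
  ses <- lapply(setNames(subs, subs), function(s) 1L)
  metrics <- metrics_from_values(vals, ses)
  em <- ancova_group(metrics, man, "fALFF", session = 1)
  expect_equal(em$t_value, rep(0, 86))
  expect_equal(em$coefficient, rep(0, 86))
})

test_that("ANCOVA matches a normal-equations + t-distribution oracle", {
  man <- toy_manifest(n_tbi = 5, n_hc = 5, seed = 9)
  subs <- unique(man$subject_id)
  set.seed(31)
  vals <- lapply(setNames(subs, subs), function(s) rnorm(86))
  ses <- lapply(setNames(subs, subs), function(s) 1L)
  metrics <- metrics_from_values(vals, ses)
  em <- ancova_group(metrics, man, "fALFF", session = 1)

  covs <- dplyr::distinct(man, subject_id, group, age, sex)
  covs <- covs[match(subs, covs$subject_id), ]
  x <- cbind(1, as.numeric(covs$group == "TBI"), covs$age,
             as.numeric(covs$sex == "M"))
  xtx_inv <- solve(t(x) %*% x)
  df <- nrow(x) - 4
  for (r in c(0, 17, 85)) {
    y <- vapply(subs, function(s) vals[[s]][r + 1], numeric(1))
    beta <- xtx_inv %*% t(x) %*% y
    resid <- y - x %*% beta
    sigma2 <- sum(resid^2) / df
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    t_oracle <- beta[2] / se
    p_oracle <- 2 * pt(-abs(t_oracle), df)
    row <- em[em$region_id == r, ]
    expect_equal(row$coefficient, beta[2], tolerance = 1e-8)
    expect_equal(row$t_value, t_oracle, tolerance = 1e-8)
    expect_equal(row$p_value, p_oracle, tolerance = 1e-8)
    expect_equal(row$n, 10L)
  }
})

test_that("ANCOVA t is invariant to affine rescaling of the metric", {
  man <- toy_manifest(n_tbi = 6, n_hc = 6, seed = 2)
  subs <- unique(man$subject_id)
  set.seed(5)
  vals <- lapply(setNames(subs, subs), function(s) rnorm(86, 10))
  ses <- lapply(setNames(subs, subs), function(s) 1L)
  m1 <- metrics_from_values(vals, ses)
  m2 <- m1
  m2$value <- m2$value * 4.2 - 17
  em1 <- ancova_group(m1, man, "fALFF")
  em2 <- ancova_group(m2, man, "fALFF")
  expect_equal(em1$t_value, em2$t_value, tolerance = 1e-9)
  expect_equal(em2$coefficient, em1$coefficient * 4.2, tolerance = 1e-9)
  # eta^2 identity for a single-df contrast
  expect_equal(em1$eta_squared,
               em1$t_value^2 / (em1$t_value^2 + (12 - 4)),
               tolerance = 1e-9)
  expect_true(all(em1$eta_squared >= 0 & em1$eta_squared <= 1))
})

test_that("rank-deficient ANCOVA designs fail with the collinear column named", {
  man <- toy_manifest(n_tbi = 5, n_hc = 5, seed = 3)
  man$sex <- "F"    # single-sex sample
  subs <- unique(man$subject_id)
  set.seed(6)
  vals <- lapply(setNames(subs, subs), function(s) rnorm(86))
  ses <- lapply(setNames(subs, subs), function(s) 1L)
  metrics <- metrics_from_values(vals, ses)
  expect_error(ancova_group(metrics, man, "fALFF"), "collinear.*sex")
})

test_that("null ANCOVA p-values are uniform across simulated cohorts", {
  man <- toy_manifest(n_tbi = 8, n_hc = 8, seed = 4)
  subs <- unique(man$subject_id)
  ses <- lapply(setNames(subs, subs), function(s) 1L)
  set.seed(77)
  pvals <- unlist(lapply(1:50, function(i) {
    vals <- lapply(setNames(subs, subs), function(s) rnorm(86))
    ancova_group(metrics_from_values(vals, ses), man, "fALFF")$p_value
  }))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ANCOVA rejection rate matches the analytic noncentral-F power", {
  n_tbi <- 16
  n_hc <- 14
  d <- 1.5
  n <- n_tbi + n_hc
  ncp <- d^2 * (n_tbi * n_hc / n)
  crit <- qf(0.95, 1, n - 4)
  power_analytic <- 1 - pf(crit, 1, n - 4, ncp = ncp)
  man <- toy_manifest(n_tbi = n_tbi, n_hc = n_hc, seed = 8)
  subs <- unique(man$subject_id)
  ses <- lapply(setNames(subs, subs), function(s) 1L)
  grp <- dplyr::distinct(man, subject_id, group)
  is_tbi <- setNames(grp$group == "TBI", grp$subject_id)
  set.seed(99)
  rej <- replicate(500, {
    vals <- lapply(setNames(subs, subs), function(s) {
      v <- rep(NA_real_, 86)
      v[1] <- rnorm(1) + d * is_tbi[[s]]
      v
    })
    em <- ancova_group(metrics_from_values(vals, ses), man, "fALFF")
    em$p_value[1] < 0.05
  })
  expect_lt(abs(mean(rej) - power_analytic), 0.03)
})

# ---- longitudinal mixed-effects model ----

lme_toy_metrics <- function(man, value_fn, metric = "fALFF") {
  long <- man[man$group == "TBI", ]
  purrr::map_dfr(seq_len(nrow(long)), function(i) {
    tibble::tibble(metric = metric, subject_id = long$subject_id[i],
                   session = long$session[i], region_id = 0:85,
                   value = value_fn(long$subject_id[i], long$session[i]))
  })
}

test_that("an exact +3 session shift is recovered with zero residual", {
  man <- toy_manifest(n_tbi = 6, n_hc = 2, seed = 10)
  set.seed(12)
  base <- lapply(setNames(unique(man$subject_id), unique(man$subject_id)),
                 function(s) rnorm(86, 5))
  metrics <- lme_toy_metrics(man, function(s, ses) {
    base[[s]] + 3.0 * (ses == 2)
  })
  em <- lme_session(metrics, man, "fALFF")
  expect_equal(em$coefficient, rep(3, 86), tolerance = 1e-6)
  expect_equal(unique(em$contrast), "session_change")
  expect_true(all(is.na(em$eta_squared)))
})

test_that("with no subject-level variance the LME matches pooled OLS", {
  man <- toy_manifest(n_tbi = 10, n_hc = 2, seed = 11)
  set.seed(13)
  metrics <- lme_toy_metrics(man, function(s, ses) {
    rnorm(86, mean = 1.0 * (ses == 2), sd = 1)
  })
  em <- lme_session(metrics, man, "fALFF")

  covs <- dplyr::distinct(man[man$group == "TBI", ], subject_id, age, sex)
  for (r in c(0, 40)) {
    d <- metrics[metrics$region_id == r, ]
    d <- dplyr::inner_join(d, covs, by = "subject_id")
    x <- cbind(1, as.numeric(d$session == 2), d$age,
               as.numeric(d$sex == "M"))
    beta <- solve(t(x) %*% x, t(x) %*% d$value)
    expect_equal(em$coefficient[em$region_id == r], beta[2],
                 tolerance = 1e-6)
  }
})

test_that("the session effect estimate is unbiased under subject heterogeneity", {
  man <- toy_manifest(n_tbi = 16, n_hc = 2, seed = 14)
  tbi_ids <- unique(man$subject_id[man$group == "TBI"])
  set.seed(15)
  est <- replicate(200, {
    intercepts <- setNames(rnorm(16, 0, 2), tbi_ids)
    metrics <- purrr::map_dfr(tbi_ids, function(s) {
      tibble::tibble(metric = "fALFF", subject_id = s, session = 1:2,
                     region_id = 0L,
                     value = intercepts[[s]] + c(0, 1) + rnorm(2, 0, 0.5))
    })
    em <- lme_session(metrics, man, "fALFF")
    em$coefficient[em$region_id == 0]
  })
  se_mean <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1), 3 * se_mean)
})

test_that("the interval random-slope variant fits and stays close to the base model", {
  man <- toy_manifest(n_tbi = 8, n_hc = 2, seed = 16)
  set.seed(17)
  base <- lapply(setNames(unique(man$subject_id), unique(man$subject_id)),
                 function(s) rnorm(86, 5))
  metrics <- lme_toy_metrics(man, function(s, ses) {
    base[[s]] + 0.8 * (ses == 2) + rnorm(86, 0, 0.2)
  })
  em0 <- lme_session(metrics, man, "fALFF")
  em1 <- lme_session(metrics, man, "fALFF", random_slope_interval = TRUE)
  expect_true(all(is.finite(em1$coefficient)))
  expect_gt(cor(em0$coefficient, em1$coefficient), 0.95)
})
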