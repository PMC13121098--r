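new_effect_map <- function(tbl) {
  class(tbl) <- c("effect_map", class(tibble::tibble()))
  tbl
}

# Subject-level covariate table: one row per subject with group, age, sex
# indicator (F = 0, M = 1).
subject_covariates <- function(manifest) {
  dplyr::distinct(manifest, .data$subject_id, .data$group, .data$age,
                  .data$sex) |>
    dplyr::mutate(sex_m = as.numeric(.data$sex == "M"),
                  group_tbi = as.numeric(.data$group == "TBI"))
}

check_full_rank <- function(x) {
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  invisible(qx)
}

#' Region-wise group ANCOVA effect map
#'
#' For every region, fits ordinary least squares of the metric on
#' `[intercept, group, age, sex]` with group coded HC = 0, TBI = 1 (so a
#' positive t means TBI > HC) and sex coded F = 0, M = 1. TBI subjects
#' contribute their designated session; controls contribute their single
#' session. Returns the group coefficient, its t statistic (coefficient /
#' SE on residual degrees of freedom), the two-sided p value, and the
#' group eta-squared. No multiple-comparison correction is applied.
#'
#' @param metrics A metric-map tibble (columns `metric`, `subject_id`,
#'   `session`, `region_id`, `value`).
#' @param manifest A validated manifest tibble.
#' @param metric Which metric to model (e.g. `"fALFF"`).
#' @param session TBI session to contrast against controls (1 or 2).
#' @param covariates Covariate columns, default `c("age", "sex")`.
#' @param eta `"partial"` (default; `SS_group / (SS_group + SS_resid)`) or
#'   `"classical"` (`SS_group / SS_total`).
#' @param subjects Optional subject-id filter (e.g. the MRI+PET-complete
#'   subset); `NULL` uses every subject with data for this metric.
#' @return An `effect_map` tibble with one row per region: `metric`,
#'   `contrast`, `region_id`, `coefficient`, `t_value`, `p_value`,
#'   `eta_squared`, `n`.
#' @export
ancova_group <- function(metrics, manifest, metric, session = 1,
                         covariates = c("age", "sex"),
                         eta = c("partial", "classical"),
                         subjects = NULL) {
  eta <- match.arg(eta)
  if (!session %in% c(1, 2)) abort("session must be 1 or 2")
  covs <- subject_covariates(manifest)
  dat <- dplyr::filter(metrics, .data$metric == !!metric)
  if (nrow(dat) == 0) abort(paste0("no data for metric ", metric))
  dat <- dplyr::inner_join(dat, covs, by = "subject_id")
  dat <- dplyr::filter(dat,
    (.data$group == "TBI" & .data$session == !!session) |
    (.data$group == "HC"))
  if (!is.null(subjects)) {
    dat <- dplyr::filter(dat, .data$subject_id %in% subjects)
  }
  subs <- dplyr::distinct(dat, .data$subject_id, .data$group_tbi,
                          .data$age, .data$sex_m)
  n_cov <- length(covariates)
  if (nrow(subs) < n_cov + 3) abort("too few subjects for the ANCOVA design")
  build_x <- function(d) {
    x <- cbind(`(intercept)` = 1, group = d$group_tbi)
    if ("age" %in% covariates) x <- cbind(x, age = d$age)
    if ("sex" %in% covariates) x <- cbind(x, sex = d$sex_m)
    x
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(dat, dplyr::all_of(c("subject_id", "region_id", "value"))),
    names_from = "region_id", values_from = "value")
  wide <- dplyr::inner_join(wide, subs, by = "subject_id")
  region_cols <- as.character(0:85)
  missing_regions <- setdiff(region_cols, names(wide))
  for (mc in missing_regions) wide[[mc]] <- NA_real_
  x_all <- build_x(wide)
  check_full_rank(x_all[complete.cases(x_all), , drop = FALSE])

  fit_region <- function(y) {
    keep <- is.finite(y) & complete.cases(x_all)
    n <- sum(keep)
    p <- ncol(x_all)
    if (n < p + 1) {
      return(c(coefficient = NA, t_value = NA, p_value = NA,
               eta_squared = NA, n = n))
    }
    x <- x_all[keep, , drop = FALSE]
    yk <- y[keep]
    if (var(yk) == 0) {
      return(c(coefficient = 0, t_value = 0, p_value = 1,
               eta_squared = 0, n = n))
    }
    check_full_rank(x)
    fit <- lm.fit(x, yk)
    rss_f <- sum(fit$residuals^2)
    df <- n - p
    xtx_inv <- chol2inv(qr.R(fit$qr))[order(fit$qr$pivot), order(fit$qr$pivot)]
    sigma2 <- rss_f / df
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    b <- unname(fit$coefficients[2])
    tval <- if (se > 0) b / se else 0
    pval <- 2 * pt(-abs(tval), df)
    red <- lm.fit(x[, -2, drop = FALSE], yk)
    ss_group <- sum(red$residuals^2) - rss_f
    e2 <- if (eta == "partial") ss_group / (ss_group + rss_f)
          else ss_group / sum((yk - mean(yk))^2)
    c(coefficient = b, t_value = tval, p_value = pval,
      eta_squared = max(0, min(1, e2)), n = n)
  }
  res <- vapply(region_cols, function(rc) fit_region(wide[[rc]]), numeric(5))
  new_effect_map(tibble::tibble(
    metric = metric,
    contrast = paste0("group_ses", session),
    region_id = 0:85,
    coefficient = as.numeric(res["coefficient", ]),
    t_value = as.numeric(res["t_value", ]),
    p_value = as.numeric(res["p_value", ]),
    eta_squared = as.numeric(res["eta_squared", ]),
    n = as.integer(res["n", ])))
}

#' Region-wise longitudinal mixed-effects effect map
#'
#' For injured subjects with both sessions, fits per region the linear
#' mixed-effects model `metric ~ session + age + sex + (1 | subject)` by
#' REML, sessions coded 0/1. With `random_slope_interval = TRUE` the
#' number of days between scans additionally enters as a subject-level
#' random slope. The session fixed-effect coefficient is the quantity
#' correlated across modalities for the change-vs-change comparisons; its
#' t statistic uses the asymptotic SE with residual-based degrees of
#' freedom (n - p fixed effects). Boundary (singular) variance estimates
#' are retained and flagged; a non-converging region falls back to pooled
#' OLS, flagged `"ols_fallback"`.
#'
#' @inheritParams ancova_group
#' @param random_slope_interval Add `(0 + days_between_scans | subject)`.
#' @return An `effect_map` tibble (`contrast = "session_change"`,
#'   `eta_squared` absent/NA) with a `flag` column.
#' @export
lme_session <- function(metrics, manifest, metric,
                        covariates = c("age", "sex"),
                        random_slope_interval = FALSE,
                        subjects = NULL) {
  covs <- subject_covariates(manifest)
  long_ids <- longitudinal_subjects(manifest)
  if (!is.null(subjects)) long_ids <- intersect(long_ids, subjects)
  if (length(long_ids) < 3) abort("too few longitudinal TBI subjects")
  dat <- dplyr::filter(metrics, .data$metric == !!metric,
                       .data$subject_id %in% long_ids)
  dat <- dplyr::inner_join(dat, covs, by = "subject_id")
  dat$session01 <- as.numeric(dat$session == 2)
  if (random_slope_interval) {
    dbs <- dplyr::distinct(
      dplyr::filter(manifest, .data$subject_id %in% long_ids,
                    !is.na(.data$days_between_scans)),
      .data$subject_id, .data$days_between_scans)
    dat <- dplyr::left_join(dat, dbs, by = "subject_id")
    if (any(is.na(dat$days_between_scans))) {
      abort("days_between_scans required for the random-slope variant")
    }
  }
  form <- stats::as.formula(paste(
    "value ~ session01",
    if ("age" %in% covariates) "+ age" else "",
    if ("sex" %in% covariates) "+ sex_m" else "",
    "+ (1 | subject_id)",
    if (random_slope_interval) "+ (0 + days_between_scans | subject_id)" else ""))
  p_fixed <- 2 + sum(c("age", "sex") %in% covariates)

  fit_region <- function(d) {
    d <- d[is.finite(d$value), , drop = FALSE]
    both <- names(which(table(d$subject_id) == 2))
    d <- d[d$subject_id %in% both, , drop = FALSE]
    n <- nrow(d)
    if (length(both) < 3) {
      return(list(coefficient = NA_real_, t_value = NA_real_,
                  p_value = NA_real_, n = n, flag = "too_few_subjects"))
    }
    ols <- function(flag) {
      x <- cbind(1, d$session01,
                 if ("age" %in% covariates) d$age,
                 if ("sex" %in% covariates) d$sex_m)
      fit <- lm.fit(x, d$value)
      df <- n - ncol(x)
      rss <- sum(fit$residuals^2)
      xtx_inv <- chol2inv(qr.R(fit$qr))[order(fit$qr$pivot), order(fit$qr$pivot)]
      se <- sqrt(rss / df * xtx_inv[2, 2])
      b <- unname(fit$coefficients[2])
      tv <- if (se > 0) b / se else 0
      list(coefficient = b, t_value = tv, p_value = 2 * pt(-abs(tv), df),
           n = n, flag = flag)
    }
    res <- tryCatch({
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(form, data = d, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     check.conv.grad = "ignore",
                     check.conv.hess = "ignore"))))
      b <- lme4::fixef(fit)[["session01"]]
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))[2]
      df <- n - p_fixed
      tv <- b / se
      list(coefficient = b, t_value = tv,
           p_value = 2 * pt(-abs(tv), df), n = n,
           flag = if (lme4::isSingular(fit)) "singular_fit" else NA_character_)
    }, error = function(e) ols("ols_fallback"))
    res
  }

  coefficient <- t_value <- p_value <- rep(NA_real_, N_REGIONS)
  n_out <- rep(NA_integer_, N_REGIONS)
  flag <- rep(NA_character_, N_REGIONS)
  for (r in 0:85) {
    d <- dat[dat$region_id == r, , drop = FALSE]
    if (nrow(d) == 0) {
      n_out[r + 1] <- 0L
      flag[r + 1] <- "no_data"
      next
    }
    res <- fit_region(d)
    coefficient[r + 1] <- res$coefficient
    t_value[r + 1] <- res$t_value
    p_value[r + 1] <- res$p_value
    n_out[r + 1] <- as.integer(res$n)
    flag[r + 1] <- res$flag
  }
  new_effect_map(tibble::tibble(
    metric = metric, contrast = "session_change",
    region_id = 0:85, coefficient = coefficient,
    t_value = t_value, p_value = p_value,
    eta_squared = NA_real_, n = n_out, flag = flag))
}

#' @export
glance.effect_map <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$metric, .data$contrast),
    n_regions = sum(is.finite(.data$t_value)),
    n_sig_unc = sum(.data$p_value < 0.05, na.rm = TRUE),
    min_p = suppressWarnings(min(.data$p_value, na.rm = TRUE)),
    .groups = "drop")
}
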