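#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks). Invariant under strictly monotone transforms of either input.
#'
#' @param x,y Numeric vectors of equal length >= 3 with finite values.
#' @return The rank correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("inputs must be finite")
  }
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0) {
    abort("zero rank variance in an input")
  }
  cor(x, y, method = "spearman")
}

#' Permutation p value for a Spearman correlation
#'
#' Permutes the region assignment of `y` `n_perm` times under a fixed seed
#' and returns the two-sided permutation p value with the small-sample
#' correction: `p = (1 + #\{|r_perm| >= |r_obs|\}) / (n_perm + 1)`. The
#' caller's RNG state is left untouched. No spatial-autocorrelation-
#' preserving null is applied; with smooth effect maps the null is
#' anti-conservative, a known caveat of region-shuffling permutation
#' schemes.
#'
#' @inheritParams spearman_rho
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream (required).
#' @return p value in `[1 / (n_perm + 1), 1]`.
#' @export
permutation_pvalue <- function(x, y, n_perm = 1000, seed) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  r_obs <- spearman_rho(x, y)
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  with_seed(seed, {
    perm_mat <- vapply(seq_len(n_perm), function(i) ry[sample.int(n)],
                       numeric(n))
    r_perm <- as.numeric(cor(rx, perm_mat))
    (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  })
}

#' Cross-modal effect-map correlation table
#'
#' Correlates regional effect maps between every unordered pair of
#' metrics, for each contrast present: the t-statistic vectors for the
#' group contrasts and the session-effect coefficient vectors for the
#' longitudinal change contrast. Rows are emitted both whole-brain (86
#' regions) and cortex-only (68 regions), with permutation p values.
#'
#' @param effect_maps An `effect_map` tibble (rows from [ancova_group()]
#'   and/or [lme_session()] bound together) covering one or more metrics
#'   and contrasts.
#' @param atlas An atlas tibble (for the cortex mask).
#' @param subsets Character subset labels, any of `"whole_brain"`,
#'   `"cortex_only"`.
#' @param n_perm Permutations per test (default 1000).
#' @param seed Master seed; each table row uses a deterministic child
#'   seed.
#' @return A tibble of class `crossmodal_tbl` with columns `metric_1`,
#'   `metric_2`, `contrast`, `subset`, `n_regions`, `rho`, `p_value`.
#' @export
crossmodal_table <- function(effect_maps, atlas = default_atlas(),
                             subsets = c("whole_brain", "cortex_only"),
                             n_perm = 1000, seed = 1) {
  subsets <- match.arg(subsets, several.ok = TRUE)
  em <- tibble::as_tibble(effect_maps)
  metrics <- sort(unique(em$metric))
  contrasts <- unique(em$contrast)
  ctx <- cortex_mask(atlas)
  get_vec <- function(metric, contrast) {
    d <- dplyr::arrange(
      dplyr::filter(em, .data$metric == !!metric, .data$contrast == !!contrast),
      .data$region_id)
    if (nrow(d) == 0) return(NULL)
    if (!identical(as.integer(d$region_id), 0:85)) {
      abort("effect maps must share the canonical 86-region ordering")
    }
    if (startsWith(contrast, "group")) d$t_value else d$coefficient
  }
  rows <- list()
  for (contrast in contrasts) {
    for (i in seq_along(metrics)) {
      for (j in seq_along(metrics)) {
        if (j <= i) next
        v1 <- get_vec(metrics[i], contrast)
        v2 <- get_vec(metrics[j], contrast)
        if (is.null(v1) || is.null(v2)) next
        for (subset in subsets) {
          keep <- if (subset == "cortex_only") ctx else rep(TRUE, 86)
          keep <- keep & is.finite(v1) & is.finite(v2)
          x <- v1[keep]; y <- v2[keep]
          row_seed <- derive_seed(seed, metrics[i], metrics[j], contrast, subset)
          rows[[length(rows) + 1]] <- tibble::tibble(
            metric_1 = metrics[i], metric_2 = metrics[j],
            contrast = contrast, subset = subset, n_regions = sum(keep),
            rho = spearman_rho(x, y),
            p_value = permutation_pvalue(x, y, n_perm = n_perm,
                                         seed = row_seed))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("crossmodal_tbl", class(out))
  out
}

#' Partial Spearman correlations of global metrics with outcomes
#'
#' Rank-transforms a per-subject global metric, an outcome score, and the
#' covariates, residualises the metric and outcome ranks on the covariate
#' ranks (with intercept), and Pearson-correlates the residuals — the
#' usual all-ranked Spearman partial correlation, under which an outcome
#' identical to a covariate is fully explained. p values use the t
#' approximation on `n - 2 - k` degrees of freedom.
#'
#' @param data A per-subject tibble holding the metric, outcome, and
#'   covariate columns.
#' @param metrics Character vector of metric column names.
#' @param outcomes Character vector of (z-scored) outcome column names.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return A tibble with columns `metric`, `outcome`, `n`, `r_partial`,
#'   `p_value`.
#' @export
partial_spearman_outcomes <- function(data, metrics, outcomes,
                                      covariates = character()) {
  purrr::map_dfr(metrics, function(m) {
    purrr::map_dfr(outcomes, function(o) {
      cols <- c(m, o, covariates)
      d <- data[, cols, drop = FALSE]
      d <- d[complete.cases(d), , drop = FALSE]
      n <- nrow(d)
      k <- length(covariates)
      if (n < k + 3) abort("insufficient complete cases")
      rm_ <- rank(d[[m]])
      ro_ <- rank(d[[o]])
      if (k > 0) {
        z <- cbind(1, vapply(covariates, function(cv) rank(d[[cv]]),
                             numeric(n)))
        rm_ <- lm.fit(z, rm_)$residuals
        ro_ <- lm.fit(z, ro_)$residuals
      } else {
        rm_ <- rm_ - mean(rm_)
        ro_ <- ro_ - mean(ro_)
      }
      if (sd(rm_) < n * 1e-10 || sd(ro_) < n * 1e-10) {
        r <- 0
        p <- 1
      } else {
        r <- cor(rm_, ro_)
        df <- n - 2 - k
        tv <- r * sqrt(df / max(1e-300, 1 - r^2))
        p <- 2 * pt(-abs(tv), df)
      }
      tibble::tibble(metric = m, outcome = o, n = n, r_partial = r,
                     p_value = p)
    })
  })
}

#' Whole-brain global metric averages per subject
#'
#' Unweighted mean of a metric over the 86 regions, per subject and
#' session.
#'
#' @param metrics A metric-map tibble.
#' @return A tibble with `metric`, `subject_id`, `session`,
#'   `global_value`.
#' @export
global_metrics <- function(metrics) {
  dplyr::summarise(
    dplyr::group_by(metrics, .data$metric, .data$subject_id, .data$session),
    global_value = mean(.data$value, na.rm = TRUE), .groups = "drop")
}
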