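# Shared fixtures, all generated in code.

test_atlas <- function() default_atlas()

# Minimal manifest: n_tbi TBI subjects with two sessions, n_hc controls.
toy_manifest <- function(n_tbi = 2, n_hc = 2, seed = 42) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    tbi <- tibble::tibble(
      subject_id = rep(sprintf("t%02d", seq_len(n_tbi)), each = 2),
      group = "TBI",
      age = rep(round(runif(n_tbi, 20, 70)), each = 2),
      sex = rep(sample(c("F", "M"), n_tbi, replace = TRUE), each = 2),
      session = rep(1:2, n_tbi),
      days_between_scans = rep(round(runif(n_tbi, 200, 300)), each = 2))
    hc <- tibble::tibble(
      subject_id = sprintf("h%02d", seq_len(n_hc)),
      group = "HC",
      age = round(runif(n_hc, 20, 80)),
      sex = sample(c("F", "M"), n_hc, replace = TRUE),
      session = 1L,
      days_between_scans = NA_real_)
    validate_manifest(dplyr::bind_rows(tbi, hc))
  })
}

# Random symmetric matrix with exact symmetry.
random_symmetric <- function(n = 86, seed = 1, fn = rnorm) {
  set.seed(seed)
  m <- matrix(fn(n * n), n)
  (m + t(m)) / 2
}

# Random FC-valid symmetric matrix (entries in [-1, 1], unit diagonal).
random_fc_values <- function(seed = 1) {
  m <- random_symmetric(seed = seed, fn = function(k) runif(k, -0.8, 0.8))
  diag(m) <- 1
  m
}

# Metric map tibble from a subjects x regions matrix of values.
metric_map_from_matrix <- function(values, subject_ids, metric = "fALFF",
                                   session = 1) {
  tibble::tibble(
    metric = metric,
    subject_id = rep(subject_ids, each = ncol(values)),
    session = session,
    region_id = rep(0:(ncol(values) - 1), length(subject_ids)),
    value = as.numeric(t(values)))
}

# Frame schedule used throughout PET tests.
test_schedule <- pet_frame_schedule()
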