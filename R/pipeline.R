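#' Extract all four regional biomarkers from a cohort
#'
#' Runs the full extraction chain on every subject-session of a
#' (synthetic or user-assembled) cohort: outlier censoring, 24-motion +
#' aCompCor + DCT nuisance regression, run-averaged FC and positive node
#' strength, run-averaged fALFF, volume-normalised SC with control-based
#' edge sparsification and row-sum node strength, and reference-Logan
#' BP_ND maps.
#'
#' @param cohort A `tbi_cohort` from [simulate_cohort()].
#' @param t_star Logan linear-segment start (seconds).
#' @param k2_ref Optional reference efflux rate (1/s) for the Logan fit.
#' @param low_band,full_band fALFF bands (Hz).
#' @return A metric-map tibble (`metric`, `subject_id`, `session`,
#'   `region_id`, `value`).
#' @export
extract_cohort_metrics <- function(cohort, t_star = 600, k2_ref = NULL,
                                   low_band = c(0.01, 0.09),
                                   full_band = c(0.008, 0.625)) {
  manifest <- cohort$manifest
  atlas <- cohort$atlas
  volumes <- atlas$volume[order(atlas$region_id)]
  rows <- list()
  emit <- function(metric, sid, ses, values) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      metric = metric, subject_id = sid, session = ses,
      region_id = 0:85, value = values)
  }
  # fMRI metrics
  for (key in names(cohort$bold)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    sid <- parts[1]
    ses <- as.integer(parts[2])
    b <- cohort$bold[[key]]
    den <- lapply(c("ap", "pa"), function(run) {
      ts <- b[[run]]
      motion <- b[[paste0("motion_", run)]]
      noise <- b[[paste0("noise_", run)]]
      cens <- detect_outliers(ts, motion)
      nuis <- nuisance_set(motion, noise, ts$dt)
      denoise(ts, nuis, censor = cens)
    })
    fc <- fc_matrix(den[[1]], den[[2]])
    emit("FC_strength", sid, ses, fc_node_strength(fc))
    emit("fALFF", sid, ses,
         falff_runs(den[[1]], den[[2]], low_band, full_band))
  }
  # SC metrics: normalise all matrices, then sparsify on session-1 controls
  if (length(cohort$sc_counts) > 0) {
    keys <- names(cohort$sc_counts)
    mats <- lapply(keys, function(k) {
      sc_from_counts(cohort$sc_counts[[k]]$counts, volumes)
    })
    sid_of <- vapply(keys, function(k) strsplit(k, ".", fixed = TRUE)[[1]][1], "")
    grp_of <- manifest$group[match(sid_of, manifest$subject_id)]
    sp <- control_sparsify(mats, is_control = grp_of == "HC")
    for (i in seq_along(keys)) {
      parts <- strsplit(keys[i], ".", fixed = TRUE)[[1]]
      emit("SC_strength", parts[1], as.integer(parts[2]),
           sc_node_strength(sp$matrices[[i]]))
    }
  }
  # PET metric
  for (key in names(cohort$tacs)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    bmap <- bpnd_map(cohort$tacs[[key]]$tac, t_star = t_star,
                     k2_ref = k2_ref, subject_id = parts[1],
                     session = as.integer(parts[2]))
    emit("BPND", parts[1], as.integer(parts[2]), bmap$value)
  }
  dplyr::bind_rows(rows)
}

#' Build effect maps for every metric and contrast
#'
#' Group ANCOVA maps at each session and the TBI-only longitudinal
#' mixed-effects map, for each metric present in the data.
#'
#' @param metrics A metric-map tibble.
#' @param manifest A validated manifest tibble.
#' @param contrasts Which contrasts to fit.
#' @param covariates Covariates for every model.
#' @param random_slope_interval Passed to [lme_session()].
#' @return An `effect_map` tibble covering all metric-contrast pairs.
#' @export
effect_maps <- function(metrics, manifest,
                        contrasts = c("group_ses1", "group_ses2",
                                      "session_change"),
                        covariates = c("age", "sex"),
                        random_slope_interval = FALSE) {
  present <- unique(metrics$metric)
  maps <- list()
  for (m in present) {
    if ("group_ses1" %in% contrasts) {
      maps[[length(maps) + 1]] <-
        ancova_group(metrics, manifest, m, session = 1,
                     covariates = covariates)
    }
    if ("group_ses2" %in% contrasts) {
      maps[[length(maps) + 1]] <-
        ancova_group(metrics, manifest, m, session = 2,
                     covariates = covariates)
    }
    if ("session_change" %in% contrasts) {
      maps[[length(maps) + 1]] <-
        lme_session(metrics, manifest, m, covariates = covariates,
                    random_slope_interval = random_slope_interval)
    }
  }
  new_effect_map(dplyr::bind_rows(maps))
}

#' Validate a pipeline configuration
#'
#' @param config A named list (or path to a YAML file) with optional
#'   blocks `simulation` (arguments to [simulation_spec()]), `falff`
#'   (`low_band`, `full_band`), `logan` (`t_star`, `k2_ref`),
#'   `crossmodal` (`n_perm`, `subsets`), and a master `seed`.
#' @return The validated config list, with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  def <- list(seed = 1,
              simulation = list(),
              falff = list(low_band = c(0.01, 0.09),
                           full_band = c(0.008, 0.625)),
              logan = list(t_star = 600, k2_ref = NULL),
              crossmodal = list(n_perm = 1000,
                                subsets = c("whole_brain", "cortex_only")),
              random_slope_interval = FALSE)
  config <- utils::modifyList(def, config, keep.null = TRUE)
  sim_args <- config$simulation
  sim_args$seed <- config$seed
  spec <- do.call(simulation_spec, sim_args)
  nyq <- 1 / (2 * spec$bold$dt)
  if (config$falff$full_band[2] > nyq + 1e-12) {
    abort(sprintf(
      "fALFF full band upper edge %g Hz exceeds Nyquist %g Hz",
      config$falff$full_band[2], nyq))
  }
  if (config$falff$low_band[1] >= config$falff$low_band[2]) {
    abort("fALFF low band edges must be increasing")
  }
  if (config$crossmodal$n_perm < 1) abort("n_perm must be >= 1")
  config$spec <- spec
  config
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> extract -> effect models -> cross-modal correlation, with
#' every output written as plain TSV plus a machine-readable provenance
#' record (config hash, seed, package version). Re-running with an
#' identical config reproduces all outputs byte-for-byte.
#'
#' @param config A config list or YAML path (see [validate_config()]).
#' @param out_dir Output directory (created if needed).
#' @param write_signals Also write per-subject signal files (BOLD runs,
#'   motion/noise tables, TACs, count matrices). Off by default; the
#'   summary tables are always written.
#' @return Invisibly, a list with `metrics`, `effects`, `crossmodal`,
#'   `provenance`.
#' @export
run_pipeline <- function(config, out_dir, write_signals = FALSE) {
  config_in <- if (is.character(config)) yaml::read_yaml(config) else config
  config <- validate_config(config_in)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config$spec)
  metrics <- extract_cohort_metrics(
    cohort, t_star = config$logan$t_star, k2_ref = config$logan$k2_ref,
    low_band = config$falff$low_band, full_band = config$falff$full_band)
  effects <- effect_maps(metrics, cohort$manifest,
                         random_slope_interval = config$random_slope_interval)
  xmod <- crossmodal_table(effects, atlas = cohort$atlas,
                           subsets = config$crossmodal$subsets,
                           n_perm = config$crossmodal$n_perm,
                           seed = derive_seed(config$seed, "crossmodal"))
  cfg_hash <- rlang::hash(config_in)
  prov <- list(config_hash = cfg_hash, seed = config$seed,
               package = "tbifuse",
               version = as.character(utils::packageVersion("tbifuse")))
  wt <- function(x, name) {
    utils::write.table(
      cbind(x, config_hash = cfg_hash), file.path(out_dir, name),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(cohort$manifest, "manifest.tsv")
  wt(metrics, "metric_maps.tsv")
  wt(tibble::as_tibble(effects), "effect_maps.tsv")
  wt(tibble::as_tibble(xmod), "crossmodal.tsv")
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (write_signals) {
    sig_dir <- file.path(out_dir, "signals")
    dir.create(sig_dir, showWarnings = FALSE)
    for (key in names(cohort$tacs)) {
      write_tacs(cohort$tacs[[key]]$tac,
                 file.path(sig_dir, paste0("tac_", key, ".tsv")))
    }
    for (key in names(cohort$sc_counts)) {
      utils::write.table(cohort$sc_counts[[key]]$counts,
                         file.path(sig_dir, paste0("sc_counts_", key, ".tsv")),
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    for (key in names(cohort$bold)) {
      b <- cohort$bold[[key]]
      for (run in c("ap", "pa")) {
        utils::write.table(
          b[[run]]$data,
          file.path(sig_dir, sprintf("bold_%s_%s.tsv", run, key)),
          sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
        utils::write.table(
          b[[paste0("motion_", run)]],
          file.path(sig_dir, sprintf("motion_%s_%s.tsv", run, key)),
          sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
      }
    }
  }
  invisible(list(metrics = metrics, effects = effects, crossmodal = xmod,
                 provenance = prov))
}
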