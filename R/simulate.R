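#' Pair of effect fields with a planted rank correlation
#'
#' Draws two regional effect fields from a Gaussian copula whose latent
#' Pearson correlation `2 sin(pi rho / 6)` yields a population Spearman
#' correlation of exactly `rho`; any rank-preserving transform of either
#' field keeps that rank correlation.
#'
#' @param seed Integer seed.
#' @param rho Target population Spearman correlation in `[-1, 1]`.
#' @param n Number of regions (default 86).
#' @return A list with standard-normal numeric vectors `x` and `y`.
#' @export
make_effect_fields <- function(seed, rho, n = N_REGIONS) {
  if (abs(rho) > 1) abort("|rho| must be <= 1")
  r_pearson <- 2 * sin(pi * rho / 6)
  with_seed(seed, {
    z1 <- rnorm(n)
    z2 <- r_pearson * z1 + sqrt(1 - r_pearson^2) * rnorm(n)
    list(x = z1, y = z2)
  })
}

#' Synthetic multimodal cohort specification
#'
#' Bundles every parameter of the synthetic cohort generator. Defaults
#' emulate the study design: 16 TBI subjects with two MRI sessions and 14
#' single-session MRI controls; 7 of the TBI subjects and 19 controls
#' (9 overlapping the MRI controls) have PET. BOLD runs are 420 volumes at
#' TR 0.8 s (two runs, AP/PA); PET uses the 22-frame, 60-minute schedule
#' with SRTM kinetics (R1 = 1, k2 = 0.3/min); SC counts are symmetric
#' negative-binomial draws around volume-structured means.
#'
#' @param seed Master seed; all per-subject streams derive from it.
#' @param n_tbi_mri,n_hc_mri,n_tbi_pet,n_hc_pet Per-modality sample sizes.
#' @param n_hc_overlap How many PET controls also have MRI; defaults to
#'   the study's 9, capped at the smaller control group.
#' @param target_cross_modal_rho Planted population Spearman correlation
#'   between the group-effect fields of the two `rho_pair` metrics.
#' @param rho_pair Length-2 character: which metrics' group-effect fields
#'   are correlated (default fALFF and SC strength).
#' @param effect_scales Named list of group/session effect SDs per metric
#'   (on the generator's native scale for that metric).
#' @param subject_jitter_sd Between-subject SD of regional effects.
#' @param bold List: `n_time`, `dt`, `sigma_broadband` (broadband noise SD
#'   relative to the unit-SD band-limited signal), `n_spikes` (motion
#'   spikes per run), `spike_mm`, `physio_amp`, `n_noise_vox`.
#' @param pet List: `R1`, `k2` (1/s), `bp_baseline`, `noise_frac`
#'   (relative SD on a 60-s frame; scales as 1/sqrt(duration)),
#'   `grid_dt`, and gamma-variate reference parameters `A`, `alpha`,
#'   `beta`.
#' @param sc List: `base_mean` (mean streamline count per retained edge),
#'   `dispersion` (negative-binomial size), `zero_frac` (fraction of edges
#'   structurally zero in controls).
#' @param atlas Atlas tibble.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1,
                            n_tbi_mri = 16, n_hc_mri = 14,
                            n_tbi_pet = 7, n_hc_pet = 19,
                            n_hc_overlap = NULL,
                            target_cross_modal_rho = 0.6,
                            rho_pair = c("fALFF", "SC_strength"),
                            effect_scales = list(
                              fALFF = c(group = 0.25, session = 0.10),
                              SC_strength = c(group = 0.25, session = 0.10),
                              BPND = c(group = 0.40, session = 0.15),
                              FC_strength = c(group = 0.15, session = 0.06)),
                            subject_jitter_sd = 0.05,
                            bold = list(),
                            pet = list(),
                            sc = list(),
                            atlas = default_atlas()) {
  if (n_tbi_mri < 1 || n_hc_mri < 1 || n_tbi_pet < 1 || n_hc_pet < 1) {
    abort("all sample sizes must be >= 1")
  }
  if (n_tbi_pet > n_tbi_mri) abort("PET TBI subjects are a subset of MRI TBI")
  if (is.null(n_hc_overlap)) n_hc_overlap <- min(n_hc_mri, n_hc_pet, 9)
  if (n_hc_overlap < 0 || n_hc_overlap > min(n_hc_mri, n_hc_pet)) {
    abort("n_hc_overlap must lie in [0, min(n_hc_mri, n_hc_pet)]")
  }
  if (abs(target_cross_modal_rho) > 1) abort("|rho| must be <= 1")
  known <- c("BPND", "fALFF", "FC_strength", "SC_strength")
  if (!all(rho_pair %in% known) || length(rho_pair) != 2) {
    abort("rho_pair must name two distinct metrics")
  }
  bold_def <- list(n_time = 420L, dt = 0.8, sigma_broadband = 0.5,
                   n_spikes = 2L, spike_mm = 1.5, physio_amp = 0.15,
                   n_noise_vox = 30L)
  pet_def <- list(R1 = 1, k2 = 0.3 / 60, bp_baseline = 2,
                  noise_frac = 0.05, grid_dt = 1,
                  A = 20, alpha = 1.2, beta = 240)
  sc_def <- list(base_mean = 200, dispersion = 10, zero_frac = 0.10)
  bold <- utils::modifyList(bold_def, bold)
  pet <- utils::modifyList(pet_def, pet)
  sc <- utils::modifyList(sc_def, sc)
  if (bold$sigma_broadband < 0 || sc$dispersion <= 0 || pet$noise_frac < 0) {
    abort("noise scales must be non-negative (dispersion > 0)")
  }
  if (pet$bp_baseline < 0) abort("baseline BP_ND must be >= 0")
  structure(list(seed = as.integer(seed),
                 n_tbi_mri = n_tbi_mri, n_hc_mri = n_hc_mri,
                 n_tbi_pet = n_tbi_pet, n_hc_pet = n_hc_pet,
                 n_hc_overlap = n_hc_overlap,
                 target_cross_modal_rho = target_cross_modal_rho,
                 rho_pair = rho_pair, effect_scales = effect_scales,
                 subject_jitter_sd = subject_jitter_sd,
                 bold = bold, pet = pet, sc = sc, atlas = atlas),
            class = "simulation_spec")
}

# Planted regional truth: group/session effect fields per metric (unit
# normal, scaled later), with the rho_pair group fields rank-correlated at
# the target rho, plus the base FC matrix and the structural-zero edge set.
build_truth <- function(spec) {
  es <- derive_seed(spec$seed, "effects")
  metrics <- c("BPND", "fALFF", "FC_strength", "SC_strength")
  pair <- make_effect_fields(es, spec$target_cross_modal_rho)
  group_fields <- list()
  group_fields[[spec$rho_pair[1]]] <- pair$x
  group_fields[[spec$rho_pair[2]]] <- pair$y
  truth <- with_seed(derive_seed(es, "rest"), {
    for (m in setdiff(metrics, spec$rho_pair)) {
      group_fields[[m]] <- rnorm(N_REGIONS)
    }
    session_fields <- lapply(setNames(metrics, metrics),
                             function(m) rnorm(N_REGIONS))
    list(group_fields = group_fields, session_fields = session_fields)
  })
  # scale to each metric's native units
  truth$group_effect <- lapply(setNames(metrics, metrics), function(m) {
    truth$group_fields[[m]] * spec$effect_scales[[m]][["group"]]
  })
  truth$session_effect <- lapply(setNames(metrics, metrics), function(m) {
    truth$session_fields[[m]] * spec$effect_scales[[m]][["session"]]
  })
  truth$fc_base <- base_fc_matrix(spec$atlas)
  truth$sc_zero_edges <- with_seed(derive_seed(es, "sczero"), {
    ut <- which(upper.tri(matrix(0, N_REGIONS, N_REGIONS)))
    z <- matrix(FALSE, N_REGIONS, N_REGIONS)
    pick <- sample(ut, round(spec$sc$zero_frac * length(ut)))
    z[pick] <- TRUE
    z | t(z)
  })
  truth
}

# Network-structured base FC: within-network 0.3, between 0.05.
base_fc_matrix <- function(atlas) {
  net <- atlas$network[order(atlas$region_id)]
  m <- outer(net, net, `==`) * 0.25 + 0.05
  diag(m) <- 1
  m
}

# Nearest correlation-like repair: clip eigenvalues, renormalise diagonal.
make_pd_corr <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 1e-4)
  m2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m2))
  m2 / outer(d, d)
}

#' Simulate one subject-session of regional BOLD data
#'
#' Each region's series is a band-limited (0.01-0.09 Hz) unit-variance
#' signal scaled by a regional amplitude (baseline 1 plus planted group /
#' session effects and subject jitter) plus broadband noise, so the true
#' fALFF is an increasing function of the amplitude. Inter-regional
#' covariance is planted through a target FC matrix shared by the
#' band-limited and broadband parts. A six-parameter motion table with
#' occasional large-derivative spikes (mirrored as artifacts in the BOLD
#' series) and a white-matter/CSF noise-compartment table (low-rank physio
#' components that also leak weakly into the BOLD series) accompany each
#' run so the censoring and nuisance-regression stages have real work.
#'
#' @param spec A [simulation_spec()].
#' @param group `"TBI"` or `"HC"`; session 1 or 2.
#' @param session Session number.
#' @param seed Integer seed for this subject-session.
#' @param truth Optional truth list from an enclosing cohort simulation;
#'   built from `spec` if omitted.
#' @param subject_jitter Optional length-86 amplitude jitter.
#' @return A list with `ap`, `pa` ([regional_ts()]), `motion_ap`,
#'   `motion_pa` (T x 6), `noise_ap`, `noise_pa` (T x V), and
#'   `true_amplitude`.
#' @export
simulate_bold <- function(spec, group, session, seed, truth = NULL,
                          subject_jitter = NULL) {
  if (spec$bold$sigma_broadband < 0) abort("noise scale must be positive")
  if (is.null(truth)) truth <- build_truth(spec)
  n_t <- spec$bold$n_time
  dt <- spec$bold$dt
  amp <- 1 + truth$group_effect$fALFF * (group == "TBI") +
    truth$session_effect$fALFF * (group == "TBI" & session == 2)
  if (!is.null(subject_jitter)) amp <- amp + subject_jitter
  amp <- pmax(amp, 0.1)
  fc_t <- truth$fc_base
  if (group == "TBI") {
    e <- truth$group_effect$FC_strength +
      truth$session_effect$FC_strength * (session == 2)
    scale_f <- sqrt(pmax(1 + e, 0.05))
    off <- fc_t * outer(scale_f, scale_f)
    diag(off) <- 1
    fc_t <- make_pd_corr(pmin(pmax(off, -0.95), 0.95))
  }
  l_t <- t(chol(fc_t))
  freq_mask <- function(n) {
    freq <- (seq_len(n) - 1) / (n * dt)
    freq_fold <- pmin(freq, 1 / dt - freq)
    freq_fold >= 0.01 & freq_fold < 0.09
  }
  mask <- freq_mask(n_t)
  sim_run <- function(run, run_seed) {
    with_seed(run_seed, {
      # one correlated white draw; regional amplitude enters as an in-band
      # spectral gain, broadband noise as the out-of-band gain, so both
      # parts share the planted spatial covariance and the true fALFF is
      # an increasing function of the amplitude
      zb <- l_t %*% matrix(rnorm(N_REGIONS * n_t), N_REGIONS)
      f <- mvfft(t(zb))
      gain <- matrix(spec$bold$sigma_broadband, n_t, N_REGIONS)
      gain[mask, ] <- rep(amp, each = sum(mask))
      series <- t(Re(mvfft(f * gain, inverse = TRUE)) / n_t)
      # physio components shared with the noise compartment
      n_comp <- 5L
      p <- matrix(rnorm(n_t * n_comp), n_t)
      pf <- mvfft(p)
      p <- Re(mvfft(pf * mask, inverse = TRUE)) / n_t
      p <- sweep(p, 2, pmax(apply(p, 2, sd), 1e-12), `/`)
      w_bold <- matrix(rnorm(n_comp * N_REGIONS, 0, 1), n_comp)
      series <- series + spec$bold$physio_amp * t(p %*% w_bold)
      v <- spec$bold$n_noise_vox
      w_noise <- matrix(rnorm(n_comp * v, 0, 1), n_comp)
      noise_tbl <- p %*% w_noise + matrix(rnorm(n_t * v, 0, 0.3), n_t)
      # motion: slow random walk + spikes
      motion <- apply(matrix(rnorm(n_t * 6, 0, 0.002), n_t), 2, cumsum)
      motion[, 4:6] <- motion[, 4:6] / 50
      if (spec$bold$n_spikes > 0) {
        at <- sample(10:(n_t - 10), spec$bold$n_spikes)
        for (tt in at) {
          motion[tt, 1] <- motion[tt, 1] + spec$bold$spike_mm
          series[, tt] <- series[, tt] + 4 * amp
        }
      }
      list(ts = regional_ts(series, dt = dt, run = run),
           motion = motion, noise = noise_tbl)
    })
  }
  ap <- sim_run("AP", derive_seed(seed, "AP"))
  pa <- sim_run("PA", derive_seed(seed, "PA"))
  list(ap = ap$ts, pa = pa$ts, motion_ap = ap$motion, motion_pa = pa$motion,
       noise_ap = ap$noise, noise_pa = pa$noise, true_amplitude = amp)
}

#' Simulate one subject-session TAC set
#'
#' Per-region SRTM forward curves on the 22-frame schedule with planted
#' regional BP_ND (baseline plus group/session effects and subject
#' jitter), a shared gamma-variate reference input, and optional zero-mean
#' Gaussian frame noise with SD proportional to `1/sqrt(frame duration)`
#' (`noise_frac` is the relative SD, in units of the peak reference
#' activity, on a 60-s frame).
#'
#' @inheritParams simulate_bold
#' @return A list with `tac` ([tac_set()]) and `true_bp` (length 86).
#' @export
simulate_tacs <- function(spec, group, session, seed, truth = NULL,
                          subject_jitter = NULL) {
  if (is.null(truth)) truth <- build_truth(spec)
  sched <- pet_frame_schedule()
  bp <- spec$pet$bp_baseline + truth$group_effect$BPND * (group == "TBI") +
    truth$session_effect$BPND * (group == "TBI" & session == 2)
  if (!is.null(subject_jitter)) bp <- bp + subject_jitter
  bp <- pmax(bp, 0.05)
  cref_fun <- gamma_variate(spec$pet$A, spec$pet$alpha, spec$pet$beta)
  fwd <- srtm_curves(spec$pet$R1, spec$pet$k2, bp,
                     sched$frame_start, sched$frame_duration,
                     cref = cref_fun, grid_dt = spec$pet$grid_dt)
  acts <- fwd$ct
  ref <- fwd$cref
  if (spec$pet$noise_frac > 0) {
    sdk <- spec$pet$noise_frac * max(ref) * sqrt(60 / sched$frame_duration)
    acts <- with_seed(seed, {
      acts + matrix(rnorm(length(acts)), nrow(acts)) %*% diag(sdk)
    })
    acts <- pmax(acts, 1e-6)
  }
  list(tac = tac_set(sched$frame_start, sched$frame_duration, acts, ref),
       true_bp = bp)
}

#' Simulate one subject-session streamline count matrix
#'
#' Symmetric negative-binomial draws around planted means: a constant base
#' count per edge modulated multiplicatively by regional group/session
#' factors `exp(effect)`. A cohort-level subset of edges is structurally
#' zero in controls (to exercise the control-based sparsification rule)
#' while retaining ordinary means in injured subjects.
#'
#' @inheritParams simulate_bold
#' @return A list with `counts` (integer 86 x 86 symmetric) and
#'   `true_factor` (length 86).
#' @export
simulate_sc_counts <- function(spec, group, session, seed, truth = NULL,
                               subject_jitter = NULL) {
  if (is.null(truth)) truth <- build_truth(spec)
  eff <- truth$group_effect$SC_strength * (group == "TBI") +
    truth$session_effect$SC_strength * (group == "TBI" & session == 2)
  if (!is.null(subject_jitter)) eff <- eff + subject_jitter
  f <- exp(eff)
  m <- spec$sc$base_mean * outer(f, f)
  if (any(m < 0)) abort("negative mean count")
  if (group == "HC") m[truth$sc_zero_edges] <- 0
  with_seed(seed, {
    ut <- upper.tri(m)
    draws <- rnbinom(sum(ut), size = spec$sc$dispersion, mu = m[ut])
    counts <- matrix(0L, N_REGIONS, N_REGIONS)
    counts[ut] <- draws
    counts <- counts + t(counts)
    list(counts = counts, true_factor = f)
  })
}

#' Simulate a full multimodal cohort
#'
#' Builds the manifest (per-modality Ns, ages, sex, scan intervals), the
#' planted regional truth, and every subject-session's BOLD runs, TAC set
#' and SC count matrix. One master seed deterministically spawns
#' independent per-subject/per-modality streams, so a fixed seed
#' reproduces the cohort bit-for-bit.
#'
#' @param spec A [simulation_spec()].
#' @return A list of class `tbi_cohort` with elements `spec`, `atlas`,
#'   `manifest`, `truth`, `bold`, `tacs`, `sc_counts` (the last three
#'   keyed by `"<subject>.<session>"`).
#' @export
simulate_cohort <- function(spec) {
  truth <- build_truth(spec)
  manifest <- build_synthetic_manifest(spec)
  subj <- dplyr::distinct(manifest, .data$subject_id, .data$group,
                          .data$has_mri, .data$has_pet)
  bold <- list()
  tacs <- list()
  sc_counts <- list()
  for (i in seq_len(nrow(subj))) {
    sid <- subj$subject_id[i]
    grp <- subj$group[i]
    sessions <- manifest$session[manifest$subject_id == sid]
    jit_seed <- derive_seed(spec$seed, sid, "jitter")
    jit <- with_seed(jit_seed, list(
      falff = rnorm(N_REGIONS, 0, spec$subject_jitter_sd),
      bp = rnorm(N_REGIONS, 0, spec$subject_jitter_sd),
      sc = rnorm(N_REGIONS, 0, spec$subject_jitter_sd)))
    for (ses in sessions) {
      key <- paste0(sid, ".", ses)
      if (subj$has_mri[i]) {
        bold[[key]] <- simulate_bold(
          spec, grp, ses, derive_seed(spec$seed, sid, ses, "bold"),
          truth = truth, subject_jitter = jit$falff)
        sc_counts[[key]] <- simulate_sc_counts(
          spec, grp, ses, derive_seed(spec$seed, sid, ses, "sc"),
          truth = truth, subject_jitter = jit$sc)
      }
      if (subj$has_pet[i]) {
        tacs[[key]] <- simulate_tacs(
          spec, grp, ses, derive_seed(spec$seed, sid, ses, "pet"),
          truth = truth, subject_jitter = jit$bp)
      }
    }
  }
  structure(list(spec = spec, atlas = spec$atlas, manifest = manifest,
                 truth = truth, bold = bold, tacs = tacs,
                 sc_counts = sc_counts),
            class = "tbi_cohort")
}

# Manifest emulating the study: TBI subjects have two sessions; controls
# one. PET TBI subjects are a subset of the MRI TBI subjects; PET controls
# partially overlap the MRI controls.
build_synthetic_manifest <- function(spec) {
  overlap <- spec$n_hc_overlap
  n_hc_total <- spec$n_hc_mri + spec$n_hc_pet - overlap
  with_seed(derive_seed(spec$seed, "manifest"), {
    tbi_ids <- sprintf("tbi%02d", seq_len(spec$n_tbi_mri))
    hc_ids <- sprintf("hc%02d", seq_len(n_hc_total))
    tbi_age <- round(runif(spec$n_tbi_mri, 19, 73), 1)
    hc_age <- round(runif(n_hc_total, 23, 86), 1)
    # female fractions follow the study (4/16 TBI, 7 HC); always keep both
    # sexes represented so the sex covariate stays estimable
    clamp_f <- function(n, frac) {
      if (n < 2) return(0L)
      max(1L, min(n - 1L, as.integer(round(n * frac))))
    }
    nf_tbi <- clamp_f(spec$n_tbi_mri, 4 / 16)
    nf_hc <- clamp_f(n_hc_total, 7 / 24)
    tbi_sex <- sample(rep(c("F", "M"), c(nf_tbi, spec$n_tbi_mri - nf_tbi)))
    hc_sex <- sample(rep(c("F", "M"), c(nf_hc, n_hc_total - nf_hc)))
    dbs <- round(rnorm(spec$n_tbi_mri, 253, 35))
    dpi <- round(rnorm(spec$n_tbi_mri, 150, 20))
    tbi <- tibble::tibble(
      subject_id = rep(tbi_ids, each = 2),
      group = "TBI",
      age = rep(tbi_age, each = 2),
      sex = rep(tbi_sex, each = 2),
      session = rep(c(1L, 2L), spec$n_tbi_mri),
      days_post_injury = as.numeric(rbind(dpi, dpi + dbs)),
      days_between_scans = rep(as.numeric(dbs), each = 2),
      has_mri = TRUE,
      has_pet = rep(seq_len(spec$n_tbi_mri) <= spec$n_tbi_pet, each = 2))
    hc_has_mri <- seq_len(n_hc_total) <= spec$n_hc_mri
    hc_has_pet <- seq_len(n_hc_total) > (spec$n_hc_mri - overlap)
    hc <- tibble::tibble(
      subject_id = hc_ids, group = "HC", age = hc_age, sex = hc_sex,
      session = 1L, days_post_injury = NA_real_,
      days_between_scans = NA_real_,
      has_mri = hc_has_mri, has_pet = hc_has_pet)
    validate_manifest(dplyr::bind_rows(tbi, hc))
  })
}
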