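---
title: "Multimodal regional biomarker fusion: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal regional biomarker fusion: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbifuse)
```

`tbifuse` quantifies TBI-related regional pathology in four imaging
biomarkers and asks how those pathologies co-vary across modalities over
recovery. This vignette is the package's account of the science: the
models, the parameters that matter, the synthetic cohort that validates
the chain, and the design decisions taken where the methodology was
genuinely open.

## The parcellation

All quantities live on a fixed 86-region gray-matter parcellation: 68
Desikan-Killiany cortical gyri plus 18 subcortical regions. The
subcortical membership of such 86-region tables varies slightly between
laboratories and is not fully standardised; the packaged atlas uses the
common FreeSurfer aseg gray set (bilateral thalamus, caudate, putamen,
pallidum, hippocampus, amygdala, accumbens, ventral diencephalon,
cerebellar cortex) with plausible synthetic volumes and an approximate
functional-network labelling used only for plotting and the cortex-only
subsets. Any table with the same columns can replace it via
`load_atlas()`; region order in the file is the canonical order of every
vector and matrix in the package, which prevents silent cross-modality
misalignment.

## PET: binding potential by reference-region Logan analysis

The flumazenil binding potential BP_ND is a proxy for GABA-A receptor
availability and hence neuronal integrity. Dynamic PET gives each region
a time-activity curve (TAC) on a 22-frame, 60-minute schedule
(4×15 s, 4×30 s, 3×60 s, 2×120 s, 8×300 s, 1×600 s). The reference
Logan plot regresses

y(T) = ∫₀ᵀ C_T dt / C_T(T)   on   x(T) = [∫₀ᵀ C_ref dt + C_ref(T)/k2'] / C_T(T)

over late frames; the slope is the distribution volume ratio and
BP_ND = DVR − 1. Numerical choices, all configurable:

* **Time coordinate.** Frames are time-averages, so integrals are
  evaluated by piecewise-constant quadrature and the frame *midpoint* is
  the plot's time coordinate (`cumulative_integral()` itself reports
  full-frame sums, the natural "integral so far" of frame data).
* **t\*.** Default 600 s — the start of the 300-s frames, by which time
  the plot is linear for flumazenil-like kinetics. An automatic
  criterion (earliest time with ≤10% maximum relative deviation from the
  final-segment line) is available via `t_star = "auto"`.
* **The k2' term.** Both conventions (with and without the
  C_ref(T)/k2' correction) are in wide use; the default omits it, which
  is adequate once the target-to-reference ratio is near steady state,
  and `k2_ref` switches it on. In validation against the SRTM forward
  model (R1 = 1, k2 = 0.3/min), recovery is within 0.4% of truth with
  the term and within ~2% without it at BP_ND = 5; both satisfy the 2%
  recovery bound we test, and supplying the known k2 is the accurate
  choice when simulating.
* **Degenerate inputs.** A region with non-positive activity at an
  included frame, too few late frames, or a zero-variance abscissa
  raises a per-region error; `bpnd_map()` records it as a missing value
  with the reason and continues with the other 85 regions.

The simulator's forward model is the simplified reference tissue model
(SRTM): C_T = R1·C_ref + (k2 − R1·k2a)·[C_ref ⊗ e^(−k2a t)],
k2a = k2/(1+BP_ND), with a gamma-variate reference input
C_ref(t) = A·t^α·e^(−t/β) (α = 1.2, β = 240 s — an early-peaking bolus
shape). The convolution is evaluated as an exact first-order recursion
on a fine grid (default 0.5 s in `srtm_forward()`, 1 s in the cohort
generator; both well inside the ≤1 s regime where the frame-averaged
curves are accurate to ~1e−3 relative) and then frame-averaged, which is
self-consistent with the piecewise-constant integration of the Logan
stage. TAC noise is zero-mean Gaussian with SD ∝ 1/√(frame duration),
the standard count-statistics approximation; `noise_frac` is the
relative SD (in units of peak reference activity) on a 60-s frame.

## fMRI: denoising, functional connectivity, fALFF

Regional BOLD series (two runs per session, 420 volumes at TR = 0.8 s)
are first censored: a timepoint is an outlier when the framewise motion
derivative (summed |Δ| of the six rigid-body parameters, rotations
converted to mm on a 50 mm sphere — the conventional length scale that
the 0.9 mm threshold presumes) exceeds 0.9 mm, or the global signal
deviates more than 5σ from its mean. The global-signal SD is computed on
the raw regional-mean series, before any regression, so the criterion
does not depend on the nuisance model. Nuisance regression then removes
24 motion regressors ([p, p², Δp, Δp²] per parameter), 10 aCompCor
eigenvectors (top left singular vectors of the demeaned white-matter/CSF
compartment series), and a DCT high-pass basis (all DCT-II functions
with frequency < 0.008 Hz; K = 5 at T = 420, dt = 0.8). Coefficients are
estimated on non-censored timepoints only; residuals are returned
everywhere but censored indices stay flagged, and tests verify that
values at censored indices can be arbitrary without changing any
downstream output.

FC is the Pearson correlation over non-censored timepoints, averaged
element-wise across the two runs (raw-r averaging by default; Fisher-z
averaging is an option since the convention is ambiguous in practice,
and the two differ negligibly at these correlation levels). FC node
strength is the positive-only off-diagonal row sum. fALFF is the
amplitude-spectrum ratio of the 0.01–0.09 Hz band to the 0.008–0.625 Hz
band, computed per run and averaged (mirroring the FC run-averaging;
concatenation is an option). Band membership is half-open
[f_low, f_high) on the discrete FFT grid with the DC bin always
excluded — a deterministic edge-handling rule that makes the white-noise
expectation an exact bin-count ratio. The numerator band is 0.01–0.09 Hz
throughout; both edges are configurable. fALFF is invariant to positive
rescaling and always in [0, 1].

## dMRI: structural connectivity

The module's contract starts at streamline-endpoint count matrices
(tractography itself is upstream). Counts are normalised by the "total
volume of each region pair", read as the **sum** v_i + v_j — the natural
reading of "total", with the product convention available for
sensitivity analysis. False-positive edges are suppressed by the control
rule: an edge that is zero in at least 50% of control subjects
(≥ ceil(n/2), verified against a counting oracle across even and odd n)
is zeroed for every subject and session. SC node strength is the
off-diagonal row sum; sparsification can only lower it, a monotonicity
the tests assert.

## Effect maps

Cross-sectional pathology: per region, OLS of the metric on
[intercept, group, age, sex], TBI at the designated session versus
all controls (single-session by design; controls are assumed drawn from
one population). Group is coded HC = 0 / TBI = 1, so positive t means
TBI > HC; sex coding (F = 0, M = 1) is irrelevant to the group t as any
full-rank coding gives the same test. The per-region outputs are the
group coefficient, t = β/SE on n−p residual df, the two-sided p
(deliberately uncorrected — the downstream use is rank-correlating whole
maps, not thresholding single regions), and η². η² is **partial**
(SS_group/(SS_group+SS_resid)) by default, the per-coefficient
convention, with classical SS_group/SS_total as an option; for this
single-df contrast the identity η² = t²/(t²+df) holds and is tested
numerically. Rank-deficient designs (e.g. a single-sex subset) fail
loudly with the collinear column named. Regions with missing subjects
fit on complete cases and record the per-region n.

Longitudinal change: TBI subjects with both sessions, per region
metric ~ session + age + sex + (1 | subject), REML via `lme4`. The
random-intercept structure is the minimal model consistent with two
repeated measures; with the interval variant the number of days between
scans enters as an additional subject-level random slope. The session
fixed effect (sessions coded 0/1) is the quantity carried into the
cross-modal stage. The reported t uses the asymptotic SE with
residual-based df (n − p); with only two observations per subject this
is an approximation, but the downstream quantity is the coefficient,
which is estimator-robust: at a zero random-intercept boundary the fit
reduces exactly to pooled OLS (tested to 1e−6). Boundary fits are kept
and flagged `singular_fit`; a non-converging region falls back to OLS,
flagged `ols_fallback`, never silently dropped.

## Cross-modal correlation

For each unordered pair of the four metrics: Spearman rank correlation
of the group-t maps (per session) and of the session-coefficient maps,
whole-brain (86 regions) and cortex-only (68), with permutation p values
(default 1000 permutations; p = (1+k)/(n+1), two-sided, since effects in
either direction are meaningful). Permutations shuffle the region
assignment of one map. This null ignores spatial autocorrelation: with
smooth maps it is anti-conservative, a known caveat of region-shuffling
nulls — the synthetic generator plants spatially independent fields, so
calibration holds exactly in validation, and the documentation flags the
caveat for real data. Every p value is seeded and reproducible; each
table row derives its own child seed from the master seed.

Global-metric/outcome association uses the all-ranked Spearman partial
correlation: metric, outcome and covariates are rank-transformed, the
metric and outcome ranks are residualised on the covariate ranks, and
the residuals are Pearson-correlated — under this convention an outcome
identical to a covariate is exactly fully explained. The covariate set
is a required explicit argument rather than a guessed default.

## The synthetic cohort

The generator's defaults are the study conditions: 16 TBI subjects with
two MRI sessions and 14 single-session MRI controls; 7 of the TBI
subjects and 19 controls (9 overlapping the MRI controls) with PET, at
both sessions for TBI. Ages, sex ratios and scan intervals (~253 days
between sessions) follow the cohort description. One master seed spawns
per-subject/per-modality streams, so cohorts are bit-reproducible while
subjects stay independent.

Planted structure, per metric, is a regional baseline plus a group
effect (added for TBI) and a session effect (added at TBI session 2),
with small between-subject jitter (SD 0.05). The group-effect fields of
one chosen metric pair (default fALFF and SC strength) are drawn from a
Gaussian copula whose latent Pearson correlation 2·sin(πρ/6) delivers a
population Spearman correlation of exactly ρ; all other fields are
independent. Effect scales (e.g. 0.25 SD multiplicative on BOLD
amplitude and log SC counts, 0.40 additive on a baseline BP_ND of 2.0)
were chosen once as moderate, realistic effect sizes against the noise
levels below.

* **BOLD.** Band-limited (0.01–0.09 Hz) signal with the planted
  regional amplitude plus broadband noise (SD 0.5 relative to unit
  band-limited SD), implemented by spectral shaping of one spatially
  correlated white draw — band-limitation by FFT gain rather than ARMA
  fitting, so the true fALFF is an analytic, increasing function of the
  amplitude, and both spectral parts share the planted FC so the sample
  FC is centred on its target. The target FC is network-blocked
  (within 0.30, between 0.05), modulated for TBI by the planted FC
  strength effects and repaired to positive definiteness by eigenvalue
  clipping. Motion tables are slow random walks with occasional 1.5 mm
  spikes mirrored as artifacts in the series, and the noise-compartment
  table shares low-rank physio components that leak weakly into the
  BOLD — so censoring, motion regression and aCompCor all have real work
  to do in validation.
* **PET.** SRTM TACs as above with per-region planted BP_ND; default
  noise_frac 0.05.
* **SC.** Symmetric negative-binomial draws (mean 200 per retained
  edge, dispersion 10) around means modulated multiplicatively by
  exp(effect); 10% of edges are structurally zero in controls to
  exercise the sparsification rule.

What the generator does **not** emulate: voxel-level geometry and
partial-volume effects, realistic head-motion physics, arterial input
functions, lesion-driven spatially *correlated* effect fields, scanner
drift, or heterogeneity of injury location. Passing tests therefore show
that the estimators and the statistical chain are correct under the
stated generative model — they do not certify performance on real data,
where spatial autocorrelation in particular would make the permutation
null optimistic.

## Validation problem sizes

The acceptance checks run the noiseless Logan recovery at three binding
potentials plus 200 noisy replicates; fALFF checks at T = 840;
permutation calibration over 1000 replicates of 1000 permutations; and
the end-to-end recovery over 100 study-sized replicates at planted
ρ = 0.6 (detection: r > 0.4 and p < 0.05) and 100 at ρ = 0 (false-positive
control). `scripts/acceptance.R` reports the same quantities at reduced
replicate counts suitable for a quick reproduction run.

## Known limitations

* The region-shuffling permutation null is anti-conservative under
  spatial autocorrelation (no spin/variogram null is implemented).
* LME degrees of freedom are residual-based, not Satterthwaite.
* The Logan estimator carries the well-known noise-dependent negative
  bias; tests assert its monotonicity in the noise level rather than
  pretending it away.
* Voxel-level preprocessing (distortion correction, segmentation,
  tractography, smoothing) is upstream and out of scope; the package
  consumes derived regional signals.
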