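Package: tbifuse
Title: Multimodal Regional Biomarker Fusion for Longitudinal Brain Injury Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts four regional neuroimaging biomarkers from derived
    signals on an 86-region cortical/subcortical parcellation: flumazenil-PET
    binding potential (BP_ND) via reference-region Logan graphical analysis,
    structural-connectome node strength from volume-normalised streamline
    counts, and functional-connectome node strength and fractional amplitude
    of low-frequency fluctuations (fALFF) from denoised regional BOLD series.
    Builds region-wise group (ANCOVA) and longitudinal (linear mixed-effects)
    effect maps and correlates effect maps across modalities with
    permutation-based Spearman inference. Includes a synthetic multimodal
    cohort generator with planted group, session, and cross-modal effect
    structure so the full pipeline can be validated against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
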