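# Demo pipeline configuration: study-shaped synthetic cohort
# (16 TBI MRI x 2 sessions, 14 HC MRI; 7 TBI PET, 19 HC PET).
seed: 1
simulation:
  n_tbi_mri: 16
  n_hc_mri: 14
  n_tbi_pet: 7
  n_hc_pet: 19
  target_cross_modal_rho: 0.6
falff:
  low_band: [0.01, 0.09]
  full_band: [0.008, 0.625]
logan:
  t_star: 600
crossmodal:
  n_perm: 1000
  subsets: [whole_brain, cortex_only]
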