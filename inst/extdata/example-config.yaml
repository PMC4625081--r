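# Desk-scale thresholding experiment: 12 contrasts over 4 tasks, 48
# subjects in 24 families, groups of 12, thresholds Z = 0..6.
cohort:
  n_subjects: 48
  n_families: 24
  n_tasks: 4
  contrasts_per_task: 3
  grid_shape: [24, 24, 24]
  effect_amplitude: 0.85
  subject_noise_sd: 0.4
  family_noise_sd: 0.15
  smoothing_fwhm_vox: 3
  background_shared_sd: 0.05
  group_size: 12
thresholds: [0, 1, 2, 3, 4, 5, 6]
directions: [both, positive]
strategies: [cca, svi]
metrics: [pearson, spearman]
n_subsamples: 20
seed: 1
log_level: info
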