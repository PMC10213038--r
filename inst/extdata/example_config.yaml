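# Example pipeline configuration: a small synthetic cohort run end to end.
seed: 1
simulate:
  enabled: true
  write_edf: false          # set true to stream raw EEG through EDF files
  cohort:
    n_subjects: 24
    n_sessions: 4
    separation: 1.0
    effect_size: 1.0
preprocessing:
  taps: 1000
  lo: 2
  hi: 45
  threshold: 100            # microvolts, epoch-level rejection
  window: 4                 # seconds
  overlap: 0.5
clustering:
  algorithm: spectral       # or fcm
  k: 4
  m: 1.7
labeling:
  alpha: 0.05
  outlier_sd: 2.5
validation:
  enabled: true
  frac: 0.8
  folds: 10
  fractions: [0.8, 0.6, 0.4]
  M: 200
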