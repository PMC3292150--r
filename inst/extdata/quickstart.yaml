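# Quickstart pipeline configuration: 3 subjects x 2 trials, 120 s each.
# Every constant of the labeling and feature-extraction conventions is
# spelled out here so a run is fully auditable.

simulate:
  n_subjects: 3
  trials_per_subject: 2
  jitter: 0.1          # relative subject-to-subject parameter spread
  seed: 1
  duration_s: 120
  t_tf: 60             # Transition-to-Fatigue onset (s)
  t_f: 96              # Fatigue onset (s)
  mdf_start: 95        # median frequency before fatigue (Hz)
  mdf_end: 55          # median frequency at/after fatigue onset (Hz)
  amp_gain: 1.6        # relative sEMG amplitude at end of trial
  angle_hold: 90       # held elbow angle (deg)
  angle_end: 84        # post-failure elbow angle (deg)
  decline_s: 5         # seconds for the angle to fall after t_f
  osc_sd_nf: 0.2       # goniometer oscillation SD before t_tf (deg)
  osc_sd_tf: 1.0       # goniometer oscillation SD after t_tf (deg)
  noise_sd: 0.05       # goniometer sensor noise SD (deg)
  band_width_hz: 60    # width of the sEMG shaping band-pass
  fs: 2000             # sampling rate, both channels (Hz)

filter:                # acquisition-convention band-pass, dual pass
  low_hz: 1
  high_hz: 500
  order: 5

fuzzy:                 # membership breakpoints (deg / deg SD)
  angle_nf: [86.5, 89, 180, 180]     # angles above 89 -> Non-Fatigue
  angle_tf: [86.5, 87.75, 89]        # 86.5..89 band -> Transition
  angle_f: [0, 0, 86.5, 89]          # angles below 86.5 -> Fatigue
  osc_low: [0, 0, 0.4, 0.8]          # Low/High cross at 0.6 deg SD
  osc_high: [0.4, 0.8, 1000000.0, 1000000.0]
  osc_window_s: 4                    # oscillation SD block (s)

features:
  span_s: 3            # rolling-SD span (windows) for all *_std features
  channel: 1           # sEMG channel used for features (1, 2 or mean)
  fi_moments: [2]      # Dimitrov moment orders to extract (FI2 reported)
  wavelet: db3         # mother wavelet for the comparison feature
  level: 12            # decomposition depth

classify:
  train_frac: 0.5      # chronological (longitudinal) training fraction
  pairs:
    - [NF, TF]
    - [TF, F]

report:
  reference_feature: spectro_std
  dbi_spans: [1, 2, 3, 4, 5]
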