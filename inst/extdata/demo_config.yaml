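# Demo end-to-end run: venous phantom + 7-animal remodeling cohort.
seed: 42
phantom:
  baseline_radius: 4          # mm (8 mm lumen)
  elastic_modulus_true: 50    # mmHg per unit strain
  pressure_mean: 10           # mmHg, venous regime
  pressure_amplitude: 3
  cycle_period: 1             # s
  n_frames: 80
  frame_rate: 40              # Hz; two full cycles
  contour_points: 64
  noise_sd_contour: 0.02      # mm
  noise_sd_pressure: 0.1      # mmHg
  hysteresis_phase_lag: 0.3   # rad
cohort:
  n_animals: 7
  timepoints: [0, 1, 2.5, 6, 12, 24]          # months
  modulus_ratio_means: [7.3, 2.3, 1.1, 1.0, 1.4, 1.1]
  native_modulus_mean: 30
  between_animal_cv: 0.15
  measurement_cv: 0.05
modulus:
  method: loop-fit
stats:
  baseline: "0"
  log_ratio: true   # multiplicative noise -> compare on the log scale
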