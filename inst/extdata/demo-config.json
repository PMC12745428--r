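{
  "seed": 1,
  "simulation": {
    "n_per_group": 8,
    "patient_attenuation": 0.3,
    "n_trials": 8,
    "fs": 500,
    "pre_s": 1,
    "post_s": 4,
    "gap_s": 0.5,
    "tasks": "fist",
    "coupled_bands": ["alpha", "beta"],
    "noise_sd": 1,
    "mixing_strength": 0.2,
    "right_fraction": 0.125
  },
  "preprocess": {
    "bandpass": [1, 45],
    "notch": [49, 51],
    "transition_hz": 2,
    "resample_to": 250
  },
  "connectivity": {
    "bands": ["alpha", "beta"],
    "window_s": 0.4,
    "hop_s": 0.2,
    "pool_windows": true
  },
  "network": {
    "profile": [0.17, 0.22, 0.27, 0.32, 0.37, 0.42, 0.47],
    "n_realizations": 20
  },
  "stats": {
    "gate_alpha": 0.05,
    "fdr_scope": "run",
    "mas_column": "mas_upper"
  }
}
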