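{
  "out_dir": "dyadsync_run",
  "seed": 42,
  "synthetic": {
    "n_groups": 3,
    "group_size_range": [4, 6]
  },
  "preprocessing": { "threshold": 0.30, "max_gap_s": 2.0, "exclude_at": 0.10 },
  "hrv": { "band": [0.15, 0.4], "window_s": 120, "shift_s": 60, "resample_hz": 4 },
  "wavelet": {
    "omega0": 6,
    "voices": 12,
    "freq_range": [0.031, 0.5],
    "hf_band": [0.125, 0.5],
    "lf_band": [0.031, 0.125],
    "interval_s": 20,
    "story_min": 8,
    "discussion_min": 10,
    "coi_mask": true
  },
  "models": { "run": true, "screening_alpha": 0.05 }
}
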