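{
  "geometry": {
    "sid_mm": 1850,
    "separation_deg": 55,
    "frame_rate_hz": 250,
    "detector_mm": [400, 400],
    "pixel_pitch_mm": 0.25
  },
  "noise": {
    "bead_pixel_noise_sd": 0.5,
    "model_rot_noise_sd": 0.45,
    "model_trans_noise_sd": 0.4,
    "outlier_frame_prob": 0.05,
    "outlier_noise_multiplier": 4
  },
  "specimens": [
    {
      "id": "specimen2",
      "seed": 102,
      "soft_tissue_cm3": 1203,
      "noise_scale": 1
    }
  ],
  "trials": [
    {
      "id": "mini_hop",
      "specimen": "specimen2",
      "motion": "hop",
      "seed": 77796,
      "duration": 0.08
    },
    {
      "id": "mini_drop",
      "specimen": "specimen2",
      "motion": "drop",
      "seed": 77797
    }
  ],
  "normalize": {
    "hop": 75,
    "drop": 10
  }
}
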