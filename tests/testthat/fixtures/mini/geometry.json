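{
  "sid_mm": 1850,
  "separation_deg": 55,
  "frame_rate_hz": 250,
  "detector_mm": [400, 400],
  "pixel_pitch_mm": 0.25
}
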