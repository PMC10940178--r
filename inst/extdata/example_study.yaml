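# Example study configuration: two simulated subjects, reference outside
# the scanner room plus home and isocenter conditions at three field
# strengths. Times in seconds, fields in tesla, amplitudes in mV.
subjects:
  - id: s1
    seed: 101
  - id: s2
    seed: 102
conditions:
  - {location: outside, field_t: 0}
  - {location: home, field_t: 0.55}
  - {location: home, field_t: 1.5}
  - {location: home, field_t: 3}
  - {location: isocenter, field_t: 0.55}
  - {location: isocenter, field_t: 1.5}
  - {location: isocenter, field_t: 3}
simulator:
  duration_s: 120
  heart_rate_bpm: 60
  rr_jitter_sd_ms: 20
  resp_rate_bpm: 15
  noise_sd_mv: 0.01
pipeline:
  filter_low_hz: 0.67
  filter_high_hz: 150
  threshold_mv: 0.6
  margin_ms: 40
  truncation_fraction: 0.05
  fine_tol_ms: 5
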