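ty_uplift: 0.5
ty_min: 3.0
ty_max: 6.5
late_penalty_per_week: 0.25
n_calibration_anchors:
  ty:
  - 3.0
  - 6.0
  'n':
  - 57.0
  - 123.0
n_split_fractions:
- 0.3
- 0.3
- 0.4
rie_p: 2.6
grain_p_fraction: 0.7
residue_biomass_fraction: 0.15
straw_p_fraction: 0.3
k_yield_gain_fraction: 0.15
rie_k: 14.5
k_recovery_efficiency: 0.44
k_basal_threshold: 33.0
pi_offset_days: 60.0
basal_window_map:
  duration:
  - 100.0
  - 160.0
  dat:
  - 5.0
  - 21.0
zinc_sulfate_rate: 25.0
bfr_rates:
  'n': 80.0
  p: 17.0
  k: 33.0
bfr_n_split_fractions:
- 0.2
- 0.5
- 0.3
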