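# Demo configuration: small explant-like cohort plus a night-time
# neuropeptide response experiment with a TTX-blocked co-treatment group.
seed: 42
cohort:
  n_cells: 34
  rhythmic_fraction: 0.6
  sampling_interval_hr: 3
  duration_hr: 48
rhythms:
  band_low_hr: 18
  band_high_hr: 36
  order_rule: n_over_3
  n_frequencies: 2048
  max_order: 20
response:
  groups: [Vehicle, PDF, PDF+TTX]
  classes: [LNv, DN1, DN2]
  n_per_group_class: 16
  onset_hr: 1
  duration_hr: 8
  sampling_interval_hr: 1
  affected_groups: [PDF]
  affected_classes: [LNv, DN1]
  blocked_by: [TTX]
  effect_shape: ramp
  effect_size: 0.1
  reference_group: Vehicle
  family: panel
report:
  heatmap_window_hr: 24
  heatmap_ceiling: 3
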