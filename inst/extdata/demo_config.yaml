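seed: 42
out_dir: "megnet_demo"
simulation:
  n_per_group: 4
  fs: 200
  duration: 150
  bands: [alpha, beta, gamma]
  spike_rate_per_min: 0.5
  spike_amplitude_pt: 7
preprocessing:
  notch_hz: 50
  artifact_threshold_pt: 6
  spike_z: 6
  segment_length_s: 60
connectivity:
  alpha: 0.01
  use_effective_k: false
gt:
  edge_policy: positive
stats:
  parameters: [SA, DA, LA, CA]
  fc_regions: [frontal, pcc]
  sig_threshold: 0.05
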