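# example nested run configuration for the toykd protocols
seed: 42
system:
  pocket_radius: 6.0
  waters: true
sumd:
  step_window: 5000
  distance_threshold: 10.0
  temperature: 310
ttmd:
  t_start: 300
  t_increment: 10
  window_steps: 20000
  loss_threshold: -0.2
  n_replicates: 5
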