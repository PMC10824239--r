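# Demonstration configuration: simulate the default graded root-cutting
# experiment and run the whole pipeline on it.
seed: 42
simulate: {}
jip:
  eps_flat: 0.05
stats:
  params: [Fm, Fv_over_Fm, PI_abs]
  stratify: clock_time
  control_group: 0
pipeline:
  control_group: 0
  n_circles: 12
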