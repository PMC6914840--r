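# Default study configuration: the full simulation design and the model
# protocol. See ?read_run_config for the schema.
outcome_types: [linear, logistic]
sample_sizes: [20, 30, 40, 50, 60, 70, 80, 90, 100]
effect_levels: [true, false]
noise:
  low: 0.666
  high: 6.66
  k: 1000
base_seed: 42
prior:
  location: 0.0
  scale: 1.0
sampler:
  n_chains: 4
  n_iterations: 2000
  n_warmup: 1000
  thin: 1
  seed: 1
rope:
  linear: [-0.1, 0.1]
  logistic: [-0.18, 0.18]
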