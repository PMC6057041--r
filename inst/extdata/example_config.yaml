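# Example run configuration: the hypothetical two-programme comparison.
criteria: core
performance: example_performance.csv
weights:
  P1: example_weights_p1.csv
  P2: example_weights_p2.csv
sa:
  exclude: enjoyment_of_life
psa:
  n_draws: 2000
  seed: 42
  population_size: 1000
  budget_min: 5500000
  budget_max: 10000000
  budget_steps: 10
out_dir: icmcda_out
rounding:
  standardized: 2
  values: 3
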