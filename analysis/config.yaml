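# Shared settings for the numbered analysis scripts.
# The generator settings are the study conditions: a 10 x 10 county lattice
# observed over 10 years, 5 socioeconomic + 5 environmental covariates of
# which 2 environmental ones are time-invariant.
seed: 4207
generator:
  rows: 10
  cols: 10
  n_years: 10
  n_se: 5
  n_ex: 5
  n_time_invariant: 2
screening:
  vif_threshold: 5
  n_trees: 300
mcmc:
  chains: 2
  iter: 2000
  burnin: 1000
models: [1, 2, 3, 4, 5]
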