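# Example replicated sweep: confidence level x activation pattern on an
# Erdos-Renyi substrate. Reduced replicate counts; raise n_networks/n_runs
# to 15/20 for the full design.
networks:
  - model: er
    n: 1000
    mean_degree: 20
interevents:
  - family: exponential
    rate: 1
  - family: lognormal
    meanlog: 0
    sdlog: 2.7
  - family: lognormal
    meanlog: 0
    sdlog: 20
dynamics:
  mu: 0.5
  epsilon: 1.0e-4
  min_frac: 0.01
  t_max: 1.0e+06
  burn_in_factor: 10
  max_events: 2.0e+07
sweep:
  d_grid: [0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.4, 0.5]
  n_networks: 3
  n_runs: 5
  seed: 1
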