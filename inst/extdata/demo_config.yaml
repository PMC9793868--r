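# Demo run: two simulated context sessions (Day 1 / Day 2) of 40 neurons,
# 6 planted ensembles of which 3 recur on Day 2 (shared fraction 0.5).
simulation:
  n_neurons: 40
  n_ensembles: 6
  neurons_per_ensemble: 4
  max_overlap: 0.0
  duration: 120
  event_rate: 0.2
  noise_sd: 0.05
  background_rate: 0.0
  shared_fraction: 0.5
  seed: 1
factorization:
  n_restarts: 10
  rank_range: [4, 8]
cutoff_hz: 0.01
bin_frames: 4
match:
  threshold_c: 0.6
seed: 1
verbose: false
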