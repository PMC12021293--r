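# Desk-scale stability experiment: meta-learn an isolated I-to-E
# pair-based rule that holds the excitatory population at 10 Hz.
task:
  kind: stability
  variant: vogels
  scale: desk
  blocks: ie
  target_rate: 10.0
  duration_ms: 10000.0
  eval_fraction: 0.5
  eval_window_ms: 500.0
  ext_rate_range: [4.0, 10.0]
  w_mean_range: [0.05, 0.5]
  bounds: [0.0, 10.0]
  lambda_l1: 0.01
  n_trials: 4
space: small_poly
seed: 101
mode: meta_learn
max_iter: 40
popsize: 12
sigma0: 0.3
stop_loss: 0.05
snapshot_iters: [10, 15, 20]
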