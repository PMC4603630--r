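# six-species synthetic pipeline configuration used by examples and tests
species_tree: species6.nwk
seed: 20260101
simulate:
  n_classes: 30
  dup_rate: 0.1
  loss_rate: 0.2
  kappa: 0.5
  root_prob: 0.9
  drop_fraction: 0.1
model:
  kappa: 1.0
  root_prob: 0.5
optimize:
  kappa: true
  root_prob: true
  branch_lengths: false
  maxit: 200
threshold: 0.9
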