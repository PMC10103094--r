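# Example run configuration for ehrcausal::run_pipeline().
# A small synthetic smoke run: generate data, build the any-drug and
# one per-drug nonuser contrast, estimate with the unadjusted and
# one-hot L1 IPTW methods, and run the negative-control suite.
synth:
  n_persons: 2000
  n_codes: 60
  n_drugs: 4
  seed: 42
contrasts: [any_drug, nonuser]
nonuser_drugs: [fluoxetine]
methods: [unadjusted, one_hot_lr]
min_users: 10
B: 20
lambda: 0.01
seed: 42
negative_controls: true
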