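# Example configuration: the two-lever within-subjects protocol at reduced
# batch size, with a slower omission critic.
critic:
  beta_o: 0.2
protocol:
  name: ko_expl
  n_runs: 10
  seed_base: 1
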