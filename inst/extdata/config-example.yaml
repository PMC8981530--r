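# Example statincost pipeline configuration (synthetic mode).
mode: synthetic
scenarios: both
granularity: quarter
out_dir: statincost-output
cohort:
  seed: 1
  n_practices: 25
  sample_frac: 0.001
  beta: 5
  gamma: 1
  sigma: 1
  discontinuation_hazard: 0.05
  switch_prob: 0.02
policy:
  cutover_month: "2012-05"
  pre_comparator: simvastatin
  post_comparator: atorvastatin
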