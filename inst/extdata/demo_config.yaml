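# Demo run: three simulated species, every pipeline stage exercised.
seed: 42
simulate:
  n_species: 3
  segments_per_species: [8, 7, 9]
  replicates: 3
  n_orthogroups: 240
  module_n_genes: 14
  paralog_rate: 0.3
preprocess:
  min_count: 10          # detectability filter: >=10 counts in >= n-replicate samples
compartments:
  top_k: 2000            # most-variant genes entering the segment correlation
  beta_min: 0.02         # rho decay per segment below which a compartment is a block
ortho:
  hard_max: 120          # orthogroup size caps
  soft_max: 80
  balance_ratio: 3
associate:
  q_threshold: 0.05
  tf_only: true
  degree: 3
modules:
  k: auto
markers:
  ncomp: 2
  keepx_grid: [5, 10, 25]
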