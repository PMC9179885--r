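# Example snptrace pipeline config: a synthetic five-population study with
# study-shaped cohort sizes. Replace the `synthetic` section with an `input`
# section (ped/map or bed/bim/fam paths) to run on real genotypes.
seed: 1
synthetic:
  population_sizes:
    NS: 93
    LW: 44
    LR: 37
    DU: 44
    WB: 88
  n_snps: 5000
  fst: 0.2
  missing_rate: 0.015
qc:
  min_sample_call_rate: 0.95
  min_snp_call_rate: 0.95
  hwe_alpha: 0.01
  hwe_population: NS
selection:
  focal: NS
  cosmopolitan: [LR, LW, DU]
  wild: WB
plan:
  n_per_cross_training: 20
  n_per_cross_validation: 10
  n_per_purebred: 40
threshold:
  tau: 0.65
  fallback_class: HY
priors: proportional
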