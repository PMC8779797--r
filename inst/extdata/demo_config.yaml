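# Demo pipeline configuration: a small synthetic cohort with the default
# three-group structure (wild Near East, Tibetan, Chinese cultivated).
# Permutation/bootstrap counts are reduced for a fast demonstration; the
# method defaults are n_perm 20000, n_boot 1000.
simulate: true
n_perm: 1000
n_boot: 200
seed: 42
sim_config:
  n_snps: 2000
  n_chromosomes: 3
  chromosome_length: 2000000
  n_metabolites: 100
  fraction_divergent: 0.3
  seed: 42
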