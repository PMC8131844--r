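# Demo scenario: one acetate-style incubation pair at day 7.
simulate:
  enabled: true
  n_otus: 150
  frac_labeled: 0.1
  preset: acetate
  abund_sdlog: 1.5
  gc_range: [0.30, 0.50]
  assimilation_efficiency: 1.0
  composition_jitter: 0
  timepoints: [7]
  treatment: acetate
  gradient:
    bdMin: 1.674
    bdMax: 1.737
    nFractions: 12
    bandSd: 0.006
    depthPerFraction: 30000
preprocess:
  min_rel_abundance: 0.00005
  exclude_taxa: [Cyanobacteria]
  keep_singletons: false
detect:
  heavy_threshold: 1.70
  fdr: 0.10
  lfc_null: 0.25
summarize:
  rank: phylum
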