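# Small demonstration pipeline configuration (quick to run; the calibration
# settings used for recovery studies are reference_sim_config()).
seed: 42
stages:
  simulate: true
  bsa: true
  regions: true
  pheno: true
simulate:
  n_chromosomes: 1
  chrom_length_bp: 20000000
  chrom_length_cM: 80
  n_markers_per_chrom: 300
  population_type: BC1F2
  n_plants: 200
  bulk_size: 20
  mean_depth: 30
  residual_sd: 0.5
  causal_loci:
    - chrom: chr1
      pos: 15000000
      additive: 1.0
      dominance: 0.0
bsa:
  min_depth: 4
regions:
  min_snps: 3
  max_gap: 200000
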