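# Toy end-to-end configuration: a single 12-SNP locus simulated under the
# pleiotropy scenario, pushed through every analysis stage. Output paths
# are relative to output_dir (override on the command line or in R).
output_dir: finecoloc_toy_run
stages: [simulate, pics, finemap, paintor, smr, motif, aei]
simulate:
  seed: 42
  n_hap: 400
  m_snp: 12
  rho: 0.9
  maf_range: [0.1, 0.5]
  scenario: pleiotropy
  causal_gwas: 6
  causal_eqtl: 6
  lambda_gwas: 6
  lambda_eqtl: 8
  n_gwas: 100000
  n_eqtl: 500
  annotation_gamma0: -2
  annotation_gamma1: 2
pics:
  n_perm: 2000
  r2_min: 0.5
  seed: 43
finemap:
  mode: exhaustive
  k_max: 3
  prior_sd: 3
paintor:
  k_max: 1
  n_loci: 6
  max_iter: 25
smr:
  p_eqtl_max: 5.0e-5
  p_gwas_max: 0.05
  alpha_smr: 0.05
  alpha_heidi: 0.05
motif:
  p_cutoff: 1.0e-4
  seq_length: 4000
  seed: 44
aei:
  slope: 0.95
  intercept: 0.05
  noise_sd: 0.05
  n_het: 12
  true_log2_imbalance: -0.6
  seed: 45
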