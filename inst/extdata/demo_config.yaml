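# Demo pipeline configuration: a 500-sample, 2000-marker synthetic
# breeding program, analysed end to end. Run with
#   Rscript inst/scripts/run_pipeline.R --config inst/extdata/demo_config.yaml --out demo_out
seed: 20
simulate:
  n_markers: 2000
  family_sizes: {A: 37, B: 37, C: 109, D: 112, E: 45}
  t2_size: 100
  t37_size: 51
  alpha_dr: 0.05
  n_locations: 3
  n_reps: 2
qc:
  max_missing: 0.10
  min_maf: 0.05
pcoa:
  k: 2
brr:
  n_iter: 1500
  burn_in: 500
evaluation:
  trait: TW
  cv_k: 5
  cv_reps: 2
  train_gens: [T2, T3-7]
  test_gens: [T1]
  include_parents: true
heritability:
  trait: TW
  n_genotypes: 38
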