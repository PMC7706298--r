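# Example pipeline configuration for run_pipeline(); desk-scale sizes.
simulate:
  n_genotypes: 60
  n_environments: 3
  n_reps: 2
  n_blocks_per_rep: 6
  n_snps: 200
  n_causal: 50
  band_range: [650, 850]
  band_step: 10
  n_sparse_environments: 1
  informative_regions:
    start: [690]
    end: [760]
    rg: [-0.7]
  seed: 7
preprocess:
  h2_threshold: 0
  bin_width: 10
blup:
  remove_outliers: response
quantgen:
  max_missing: 0.10
  min_maf: 0.05
predict:
  n_iter: 3
  train_frac: 0.8
optimize:
  n_select: 3
  population_size: 10
  n_generations: 5
  fitness_folds: 3
  fitness_num_trees: 60
  patience: 5
evaluate:
  fractions: [0.8, 0.4]
  intensity: 0.2
  n_iter: 2
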