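# small simulation configurations shared across test files

tiny_config <- function(seed = 1, ...) {
  args <- modifyList(list(
    n_genotypes = 30, n_environments = 2, n_reps = 2, n_blocks_per_rep = 5,
    n_snps = 60, n_causal = 20, band_range = c(600, 800), band_step = 20,
    n_sparse_environments = 0,
    informative_regions = data.frame(start = 690, end = 750, rg = -0.7),
    seed = seed), list(...))
  do.call(sim_config, args)
}

small_config <- function(seed = 1, ...) {
  args <- modifyList(list(
    n_genotypes = 80, n_environments = 3, n_reps = 2, n_blocks_per_rep = 8,
    n_snps = 200, n_causal = 60, band_range = c(650, 850), band_step = 10,
    n_sparse_environments = 1,
    informative_regions = data.frame(start = 690, end = 760, rg = -0.7),
    seed = seed), list(...))
  do.call(sim_config, args)
}

# hand-built trait tables with a known linear signal, for prediction-layer
# tests that should not pay for a full simulation + REML build
toy_traits <- function(n_genotypes = 60, n_envs = 3, seed = 42,
                       noise = 0.3) {
  set.seed(seed)
  genos <- sprintf("G%03d", seq_len(n_genotypes))
  envs <- sprintf("E%02d", seq_len(n_envs))
  g <- rnorm(n_genotypes)
  x1 <- g + rnorm(n_genotypes, 0, noise)
  x2 <- -0.5 * g + rnorm(n_genotypes, 0, noise)
  m2 <- tibble::tibble(genotype = genos, seed_yield = g,
                       R705_S1 = x1, R705_S2 = x1 + rnorm(n_genotypes, 0, 0.1),
                       R815_S1 = x2, R815_S2 = x2 + rnorm(n_genotypes, 0, 0.1),
                       VREI2_S1 = -x1, VREI2_S2 = -x1,
                       CA_S1 = 0.3 * g + rnorm(n_genotypes, 0, 0.5),
                       CA_S2 = 0.3 * g + rnorm(n_genotypes, 0, 0.5),
                       CT_S2 = -0.4 * g + rnorm(n_genotypes, 0, 0.5))
  m1 <- tidyr::expand_grid(environment = envs, genotype = genos) |>
    dplyr::left_join(m2, by = "genotype") |>
    dplyr::mutate(dplyr::across(c("seed_yield", "R705_S1", "R705_S2",
                                  "R815_S1", "R815_S2"),
                                ~ .x + rnorm(dplyr::n(), 0, noise / 2)))
  structure(list(method1 = m1, method2 = m2,
                 method1_envs = envs,
                 vi_names = c("NDVI", "VREI2", "NWI", "RARSb", "RARSc",
                              "NMDI"),
                 band_features = c("R705", "R815")),
            class = "phenosel_traits")
}
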