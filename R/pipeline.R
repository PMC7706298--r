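#' Run the full phenomic-selection pipeline from a configuration
#'
#' Orchestrates simulate -> preprocess/BLUP -> quantitative genetics ->
#' prediction -> waveband optimization -> selection evaluation, writing every
#' result table plus a run manifest (configuration snapshot, seeds, removed
#' plots with reasons, retained bands, stage runtimes) to `out_dir`. Runs
#' are idempotent: the same configuration and seed reproduce identical
#' outputs.
#'
#' The configuration is a YAML file (or equivalent list) with sections
#' `simulate` (arguments of [sim_config()]; required), and optional
#' `preprocess` (`h2_threshold`, `bin_width`), `blup` (`method1_envs`,
#' `remove_outliers`), `quantgen` (`max_missing`, `min_maf`), `predict`
#' (`n_iter`, `train_frac`, `enabled`), `optimize` ([ga_config()] arguments,
#' `enabled`), `evaluate` (`fractions`, `intensity`, `n_iter`, `enabled`).
#'
#' @param config Path to a YAML file or a named list.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config))
      abort(paste0("config file not found: ", config),
            class = "phenosel_io_error")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    abort("config must be a YAML path or a list", class = "phenosel_config_error")
  if (is.null(config$simulate))
    abort("config missing required key: simulate",
          class = "phenosel_config_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  runtimes <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "phenosel_pipeline_error"))
    runtimes[[name]] <<- round(as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")), 2)
    out
  }

  sim_args <- config$simulate
  if (!is.null(sim_args$informative_regions))
    sim_args$informative_regions <-
      as.data.frame(lapply(as.data.frame(sim_args$informative_regions),
                           unlist))
  cfg <- stage("simulate", do.call(sim_config, sim_args))
  sim <- stage("simulate_panel", simulate_panel(cfg))
  write_fixture(sim, out_dir)

  pp <- modifyList(list(h2_threshold = 0, bin_width = 10), config$preprocess %||% list())
  bl <- modifyList(list(method1_envs = NULL, remove_outliers = "response"),
                   config$blup %||% list())
  traits <- stage("preprocess_blup",
                  build_trait_tables(sim, h2_threshold = pp$h2_threshold,
                                     bin_width = pp$bin_width,
                                     method1_envs = bl$method1_envs,
                                     remove_outliers = bl$remove_outliers))
  readr::write_csv(traits$method1, file.path(out_dir, "blups_method1.csv"))
  readr::write_csv(traits$method2, file.path(out_dir, "blups_method2.csv"))

  qg <- modifyList(list(max_missing = 0.10, min_maf = 0.05),
                   config$quantgen %||% list())
  qg_res <- stage("quantgen", {
    m <- snp_qc(sim$snps, qg$max_missing, qg$min_maf)
    grm <- compute_grm(m)
    h2 <- estimate_h2_snp(
      setNames(traits$method2$seed_yield, traits$method2$genotype), grm)
    vi_cols <- grep(paste0("^(", paste(traits$vi_names, collapse = "|"),
                           "|CA|CT)_S\\d$"), names(traits$method2),
                    value = TRUE)
    rg <- genetic_correlation_table(traits$method2, grm, traits = vi_cols)
    list(grm = grm, h2 = h2, rg = rg)
  })
  readr::write_csv(qg_res$rg, file.path(out_dir, "genetic_correlations.csv"))
  readr::write_csv(tidy(qg_res$h2), file.path(out_dir, "h2_snp.csv"))

  pr <- modifyList(list(n_iter = 10, train_frac = 0.8, enabled = TRUE),
                   config$predict %||% list())
  pred_res <- NULL
  if (isTRUE(pr$enabled)) {
    pred_res <- stage("predict",
                      run_cohort_experiment(traits, n_iter = pr$n_iter,
                                            train_frac = pr$train_frac,
                                            seed = cfg$seed))
    readr::write_csv(pred_res$summary,
                     file.path(out_dir, "cohort_summary.csv"))
    readr::write_csv(pred_res$results,
                     file.path(out_dir, "cohort_results.csv"))
  }

  op <- config$optimize %||% list()
  op_enabled <- op$enabled %||% TRUE
  op$enabled <- NULL
  ga_res <- NULL
  if (isTRUE(op_enabled)) {
    ga_res <- stage("optimize", {
      gcfg <- do.call(ga_config, modifyList(list(seed = cfg$seed), op))
      genos <- traits$method2$genotype
      split <- make_cv1_splits(genos, pr$train_frac, 1, cfg$seed)[[1]]
      train <- traits$method1 |>
        filter(.data$genotype %in% split$train_genotypes)
      run_ga(train, gcfg)
    })
    readr::write_csv(ga_res$log, file.path(out_dir, "ga_log.csv"))
    readr::write_csv(tibble(bin = ga_res$best_bins,
                            wavelength = ga_res$selected_wavelengths),
                     file.path(out_dir, "selected_wavebands.csv"))
  }

  ev <- modifyList(list(fractions = c(0.8, 0.6, 0.4, 0.2), intensity = 0.2,
                        n_iter = 10, enabled = TRUE),
                   config$evaluate %||% list())
  eval_res <- NULL
  if (isTRUE(ev$enabled) && !is.null(ga_res)) {
    eval_res <- stage("evaluate",
                      training_size_study(traits, ga_res$best_bins,
                                          fractions = unlist(ev$fractions),
                                          rg_table = qg_res$rg,
                                          n_iter = ev$n_iter,
                                          intensity = ev$intensity,
                                          seed = cfg$seed))
    readr::write_csv(eval_res$summary,
                     file.path(out_dir, "training_size_summary.csv"))
  }

  manifest <- list(
    package_version = as.character(packageVersion("phenosel")),
    seed = cfg$seed,
    config = config,
    removed_plots = lapply(split(traits$removed_plots,
                                 seq_len(nrow(traits$removed_plots))),
                           as.list),
    retained_bands = traits$retained_bands,
    method1_environments = traits$method1_envs,
    selected_wavebands = if (is.null(ga_res)) NULL
    else ga_res$selected_wavelengths,
    runtimes_sec = runtimes
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(sim = sim, traits = traits, quantgen = qg_res,
                 prediction = pred_res, ga = ga_res, evaluation = eval_res,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
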