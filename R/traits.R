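#' Build genotype-level trait tables from raw trial data
#'
#' Runs the full preprocessing chain and BLUP extraction in one call:
#' emergence filtering, shatter filtering (yield only), moisture adjustment
#' to 13%, scan averaging, optional repeatability-based waveband filtering,
#' 10-nm binning, vegetation indices, pass-normalised canopy temperature,
#' then REML BLUPs of every trait under both preprocessing methods:
#'
#' * Method 1 - by-environment BLUPs from the reduced model (environment
#'   terms removed), one row per genotype x environment;
#' * Method 2 - across-environment BLUPs from the full model, one row per
#'   genotype.
#'
#' Exported values default to predicted genotype means (model mean + BLUP).
#'
#' @param sim A `phenosel_sim` object (or a list with the same `plots`,
#'   `spectra`, `canopy` elements, e.g. from [read_fixture()]).
#' @param h2_threshold Repeatability cutoff for waveband filtering; 0 skips
#'   the per-band repeatability fits and retains every band.
#' @param bin_width Binning width in nm (default 10).
#' @param vis Vegetation-index registry, see [vi_registry()].
#' @param method1_envs Environments used for by-environment BLUPs; default:
#'   the environments carrying spectra (complete datasets).
#' @param remove_outliers Studentized-residual outlier pass: `"response"`
#'   (yield only, default), `"all"` traits, or `"none"`.
#' @param outlier_threshold Absolute studentized-residual cutoff (default 3).
#' @param blup_value Value exported in both trait tables: `"predicted"`
#'   (default; model mean + BLUP, the predicted genotype mean) or `"blup"`
#'   (the centred BLUP deviation).
#' @return A `phenosel_traits` list: `method1`, `method2` (wide tibbles),
#'   `plot_traits`, `bin_map`, `retained_bands`, `removed_plots`,
#'   `method1_envs`, `vi_names`, `band_features`, `repeatability`.
#' @export
build_trait_tables <- function(sim,
                               h2_threshold = 0,
                               bin_width = 10,
                               vis = vi_registry(),
                               method1_envs = NULL,
                               remove_outliers = c("response", "all", "none"),
                               outlier_threshold = 3,
                               blup_value = c("predicted", "blup")) {
  remove_outliers <- match.arg(remove_outliers)
  blup_value <- match.arg(blup_value)
  plots <- sim$plots

  emer <- filter_low_emergence(plots)
  design <- emer$retained |>
    select("environment", "replicate", "block", "pass", "plot_id", "genotype")
  removed_plots <- emer$removed |> mutate(rule = "low_emergence")

  shat <- filter_shattered(emer$retained)
  removed_plots <- bind_rows(
    removed_plots,
    shat$removed |> mutate(rule = "shatter_yield_only") |>
      select("environment", "plot_id", "rule"))
  yield_tbl <- shat$retained |>
    mutate(seed_yield = adjust_moisture(.data$seed_yield, .data$moisture)) |>
    select("environment", "plot_id", "seed_yield")

  plot_traits <- design |> left_join(yield_tbl, by = c("environment", "plot_id"))

  repeat_tbls <- list(); bin_maps <- list(); retained <- list()
  for (stage in names(sim$spectra)) {
    sp <- sim$spectra[[stage]] |>
      semi_join(design, by = c("environment", "plot_id"))
    plot_mean <- suppressWarnings(average_plot_reflectance(sp))
    plot_mean <- design |>
      inner_join(plot_mean, by = c("environment", "plot_id"))
    band_cols <- setdiff(names(plot_mean), names(design))
    if (h2_threshold > 0) {
      est <- estimate_band_repeatability(plot_mean, bands = band_cols)
      repeat_tbls[[stage]] <- est
      band_cols <- filter_bands_by_repeatability(est, h2_threshold)
      if (length(band_cols) == 0)
        abort(paste0("no bands pass the repeatability threshold at ", stage),
              class = "phenosel_validation_error")
    }
    retained[[stage]] <- as.numeric(band_cols)
    binned <- bin_wavebands(plot_mean, bands = band_cols, width = bin_width)
    bin_maps[[stage]] <- attr(binned, "bin_map")
    vis_avail <- vis[vapply(seq_len(nrow(vis)), function(i)
      !anyNA(vapply(vis$bands[[i]],
                    function(l) .find_band_column(binned, l),
                    character(1))), logical(1)), ]
    if (nrow(vis_avail) < nrow(vis))
      inform(paste0("VI(s) skipped at ", stage,
                    " (bands outside retained spectrum): ",
                    paste(setdiff(vis$name, vis_avail$name), collapse = ", ")))
    binned <- suppressWarnings(compute_vi(binned, vis_avail))
    feat_cols <- setdiff(names(binned), names(design))
    binned <- binned |>
      rename_with(~ paste0(.x, "_", stage), all_of(feat_cols)) |>
      select("environment", "plot_id", all_of(paste0(feat_cols, "_", stage)))
    plot_traits <- plot_traits |>
      left_join(binned, by = c("environment", "plot_id"))
  }

  if (!is.null(sim$canopy)) {
    can <- sim$canopy |>
      semi_join(design, by = c("environment", "plot_id"))
    if ("CT_S2" %in% names(can))
      can <- suppressWarnings(
        normalize_ct_by_pass(can, CT_S2, pass))
    can <- can |> select(-any_of("pass"))
    plot_traits <- plot_traits |>
      left_join(can, by = c("environment", "plot_id"))
  }

  design_cols <- c("environment", "replicate", "block", "pass", "plot_id",
                   "genotype")
  trait_cols <- setdiff(names(plot_traits), design_cols)

  if (remove_outliers != "none") {
    target <- if (remove_outliers == "response") intersect("seed_yield", trait_cols)
    else trait_cols
    for (tr in target) {
      d <- plot_traits |> filter(!is.na(.data[[tr]]))
      if (nrow(d) < 10) next
      fit <- fit_mixed_model(d, tr)
      res <- remove_outliers_studentized(fit, outlier_threshold)
      if (nrow(res$flagged) > 0) {
        bad <- res$flagged$plot_id
        plot_traits[[tr]][plot_traits$plot_id %in% bad] <- NA
        removed_plots <- bind_rows(
          removed_plots,
          tibble(environment = res$flagged$environment, plot_id = bad,
                 rule = paste0("studentized_outlier:", tr)))
      }
    }
  }

  if (is.null(method1_envs)) {
    method1_envs <- if (length(sim$spectra) > 0)
      sort(unique(sim$spectra[[1]]$environment))
    else sort(unique(plots$environment))
  }

  method2 <- tibble(genotype = sort(unique(plot_traits$genotype)))
  method1 <- tidyr::expand_grid(environment = method1_envs,
                                genotype = method2$genotype)
  # traits sharing a missingness pattern share the model structure, so the
  # fitted design is reused across them (lme4::refit) - hundreds of waveband
  # fits reduce to one symbolic factorization per pattern
  cache2 <- list(); cache1 <- list()
  for (tr in trait_cols) {
    d <- plot_traits |> filter(!is.na(.data[[tr]]))
    if (nrow(d) < 10 || length(unique(d$genotype)) < 3) next
    key <- rlang::hash(d$plot_id)
    b2 <- suppressMessages(blups_method2(d, tr, reuse = cache2[[key]]))
    cache2[[key]] <- b2
    method2 <- method2 |>
      left_join(select(b2, "genotype", !!tr := all_of(blup_value)),
                by = "genotype")
    envs_tr <- intersect(method1_envs, unique(d$environment))
    if (length(envs_tr) > 0) {
      key1 <- paste(key, paste(envs_tr, collapse = ","))
      b1 <- suppressMessages(
        blups_method1(d, tr, environments = envs_tr,
                      reuse = cache1[[key1]]))
      cache1[[key1]] <- b1
      method1 <- method1 |>
        left_join(select(b1, "environment", "genotype",
                         !!tr := all_of(blup_value)),
                  by = c("environment", "genotype"))
    }
  }

  structure(list(
    method1 = method1,
    method2 = method2,
    plot_traits = plot_traits,
    bin_map = bin_maps,
    retained_bands = retained,
    repeatability = repeat_tbls,
    removed_plots = removed_plots,
    method1_envs = method1_envs,
    vi_names = vis$name,
    band_features = unique(unlist(lapply(bin_maps, function(b) b$label)))
  ), class = "phenosel_traits")
}

#' @export
print.phenosel_traits <- function(x, ...) {
  cat("<phenosel_traits>\n")
  cat(sprintf("  method1: %d rows (%d environments), method2: %d genotypes\n",
              nrow(x$method1), length(x$method1_envs), nrow(x$method2)))
  cat(sprintf("  binned waveband features: %d, VIs: %s\n",
              length(x$band_features), paste(x$vi_names, collapse = ", ")))
  invisible(x)
}

#' Predictor cohorts of a trait table
#'
#' Groups predictor columns into the standard cohorts compared by the
#' pipeline: canopy traits (area, temperature), vegetation indices, their
#' union, and binned wavebands.
#'
#' @param traits A `phenosel_traits` object.
#' @return Named list of predictor column vectors.
#' @export
default_cohorts <- function(traits) {
  cols <- names(traits$method1)
  canopy <- grep("^(CA|CT)_S\\d$", cols, value = TRUE)
  vi <- grep(paste0("^(", paste(traits$vi_names, collapse = "|"), ")_S\\d$"),
             cols, value = TRUE)
  bands <- grep("^R\\d+_S\\d$", cols, value = TRUE)
  out <- list(canopy = canopy, vi = vi,
              `canopy+vi` = c(canopy, vi), wavebands = bands)
  out[vapply(out, length, integer(1)) > 0]
}
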