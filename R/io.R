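#' Read a plot-level trial table
#'
#' Reads and validates the plot record CSV: one row per experimental plot
#' with design coordinates (environment, replicate, incomplete block, pass),
#' genotype, quality covariates (stand count, shatter score, moisture) and
#' machine-harvested seed yield (kg/ha, wet).
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of plot records.
#' @export
read_plot_table <- function(path) {
  if (!file.exists(path))
    abort(paste0("plot table not found: ", path), class = "phenosel_io_error")
  required <- c("environment", "replicate", "block", "pass", "plot_id",
                "genotype", "stand_count", "shatter_score", "moisture",
                "seed_yield")
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       na = "NA")
  prob <- readr::problems(x)
  if (nrow(prob) > 0)
    abort(paste0("malformed plot table (", nrow(prob), " parsing problem(s), ",
                 "first at line ", prob$row[1], "): ", path),
          class = "phenosel_schema_error")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0)
    abort(paste0("plot table missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "phenosel_schema_error")
  bad_shatter <- which(!is.na(x$shatter_score) &
                         !(x$shatter_score %in% 1:5))
  if (length(bad_shatter) > 0)
    abort(paste0("shatter_score outside 1-5 at row(s): ",
                 paste(head(bad_shatter, 5), collapse = ", ")),
          class = "phenosel_validation_error")
  bad_moist <- which(!is.na(x$moisture) & (x$moisture < 0 | x$moisture >= 1))
  if (length(bad_moist) > 0)
    abort(paste0("moisture outside [0, 1) at row(s): ",
                 paste(head(bad_moist, 5), collapse = ", ")),
          class = "phenosel_validation_error")
  bad_stand <- which(!is.na(x$stand_count) & x$stand_count < 0)
  if (length(bad_stand) > 0)
    abort(paste0("negative stand_count at row(s): ",
                 paste(head(bad_stand, 5), collapse = ", ")),
          class = "phenosel_validation_error")
  dup <- duplicated(x[, c("environment", "plot_id")])
  if (any(dup))
    abort(paste0("duplicated (environment, plot_id) at row(s): ",
                 paste(head(which(dup), 5), collapse = ", ")),
          class = "phenosel_validation_error")
  as_tibble(x)
}

#' Read a canopy spectra table
#'
#' Reads a wide CSV with identifier columns (`environment`, `plot_id`,
#' `scan`) and one column per 1-nm (or coarser) waveband, labelled by the
#' band-centre wavelength in nm. The wavelength grid is parsed from the
#' headers and must be strictly increasing. Reflectance above 1 is retained
#' with a warning (sun-glint over bright canopies is physically possible).
#'
#' @param path Path to a CSV file.
#' @param stage Growth-stage label attached to the result (`"S1"` or `"S2"`).
#' @return Tibble of spectra with attributes `wavelengths` and `stage`.
#' @export
read_spectra <- function(path, stage = c("S1", "S2")) {
  stage <- match.arg(stage)
  if (!file.exists(path))
    abort(paste0("spectra file not found: ", path),
          class = "phenosel_io_error")
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       na = "NA")
  prob <- readr::problems(x)
  if (nrow(prob) > 0)
    abort(paste0("malformed spectra file (", nrow(prob),
                 " parsing problem(s)): ", path),
          class = "phenosel_format_error")
  id_cols <- intersect(c("environment", "plot_id", "scan"), names(x))
  band_cols <- setdiff(names(x), id_cols)
  wl <- suppressWarnings(as.numeric(band_cols))
  if (any(is.na(wl)))
    abort(paste0("non-numeric waveband column header(s): ",
                 paste(head(band_cols[is.na(wl)], 5), collapse = ", ")),
          class = "phenosel_format_error")
  if (any(diff(wl) <= 0))
    abort("waveband columns must be in strictly increasing wavelength order",
          class = "phenosel_format_error")
  refl <- as.matrix(x[, band_cols])
  if (any(refl > 1, na.rm = TRUE))
    warn(paste0("reflectance > 1 in ", sum(refl > 1, na.rm = TRUE),
                " cell(s); retained (possible sun glint)"))
  out <- as_tibble(x)
  attr(out, "wavelengths") <- wl
  attr(out, "stage") <- stage
  out
}

#' Read a genotype-by-marker matrix
#'
#' First column must be `genotype`; remaining columns are markers with codes
#' in \{0, 1, 2, NA\}.
#'
#' @param path Path to a CSV/TSV file.
#' @return Integer matrix with a `missing_rate` attribute (per marker).
#' @export
read_genotype_matrix <- function(path) {
  if (!file.exists(path))
    abort(paste0("genotype file not found: ", path),
          class = "phenosel_io_error")
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE, na = "NA")
  if (names(x)[1] != "genotype")
    abort("genotype matrix must have 'genotype' as its first column",
          class = "phenosel_format_error")
  if (anyDuplicated(names(x)[-1]) > 0)
    abort("duplicated marker IDs", class = "phenosel_format_error")
  m <- as.matrix(x[, -1])
  bad <- !is.na(m) & !(m %in% c(0, 1, 2))
  if (any(bad))
    abort(paste0("invalid genotype code(s) (not 0/1/2/NA): ",
                 paste(head(unique(m[bad]), 5), collapse = ", ")),
          class = "phenosel_format_error")
  storage.mode(m) <- "integer"
  rownames(m) <- x$genotype
  attr(m, "missing_rate") <- colMeans(is.na(m))
  m
}

#' Write a simulated dataset to a fixture directory
#'
#' Emits the standard file layout: `plots.csv`, `spectra_S1.csv`,
#' `spectra_S2.csv`, `canopy.csv`, `snps.csv`, `truth.yaml`, `config.yaml`.
#' The layout round-trips losslessly through [read_fixture()].
#'
#' @param sim A `phenosel_sim` object from [simulate_panel()].
#' @param dir Existing writable directory.
#' @return Invisibly, the vector of files written.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "phenosel_sim"))
  if (!dir.exists(dir))
    abort(paste0("fixture directory does not exist: ", dir),
          class = "phenosel_io_error")
  files <- character(0)
  w <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_csv(x, p, na = "NA")
    p
  }
  files <- c(files, w(sim$plots, "plots.csv"))
  for (stage in names(sim$spectra))
    files <- c(files, w(sim$spectra[[stage]],
                        paste0("spectra_", stage, ".csv")))
  files <- c(files, w(sim$canopy, "canopy.csv"))
  snps_df <- bind_cols(tibble(genotype = rownames(sim$snps)),
                       as_tibble(sim$snps))
  files <- c(files, w(snps_df, "snps.csv"))

  truth_path <- file.path(dir, "truth.yaml")
  yaml::write_yaml(list(
    true_genetic_values = as.list(setNames(sim$truth$true_genetic_values$value,
                                           sim$truth$true_genetic_values$genotype)),
    true_band_rg = list(wavelength = sim$truth$true_band_rg$wavelength,
                        rg = sim$truth$true_band_rg$rg),
    true_band_h2 = list(wavelength = sim$truth$true_band_h2$wavelength,
                        h2 = sim$truth$true_band_h2$h2),
    true_h2_snp = sim$truth$true_h2_snp,
    variances = sim$truth$variances,
    causal_snps = sim$truth$causal_snps,
    complete_environments = sim$truth$complete_environments
  ), truth_path)
  files <- c(files, truth_path)

  cfg_path <- file.path(dir, "config.yaml")
  cfg <- unclass(sim$config)
  cfg$informative_regions <- as.list(cfg$informative_regions)
  yaml::write_yaml(cfg, cfg_path)
  files <- c(files, cfg_path)
  invisible(files)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' Environments present in the plot table but absent from the spectra files
#' are reported as sparse (phenomics not collected there).
#'
#' @param dir Fixture directory.
#' @return A list with `plots`, `spectra`, `canopy`, `snps`,
#'   `sparse_environments`.
#' @export
read_fixture <- function(dir) {
  if (!dir.exists(dir))
    abort(paste0("fixture directory does not exist: ", dir),
          class = "phenosel_io_error")
  plots <- read_plot_table(file.path(dir, "plots.csv"))
  spectra <- list()
  for (stage in c("S1", "S2")) {
    p <- file.path(dir, paste0("spectra_", stage, ".csv"))
    if (file.exists(p)) spectra[[stage]] <- read_spectra(p, stage)
  }
  canopy_path <- file.path(dir, "canopy.csv")
  canopy <- if (file.exists(canopy_path))
    readr::read_csv(canopy_path, show_col_types = FALSE, progress = FALSE,
                    na = "NA") else NULL
  snps <- read_genotype_matrix(file.path(dir, "snps.csv"))
  spectra_envs <- unique(unlist(lapply(spectra, function(s) s$environment)))
  sparse <- setdiff(unique(plots$environment), spectra_envs)
  if (length(sparse) > 0)
    inform(paste0("sparse environments (no spectra): ",
                  paste(sparse, collapse = ", ")))
  list(plots = plots, spectra = spectra, canopy = canopy, snps = snps,
       sparse_environments = sparse)
}
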