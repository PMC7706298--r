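#' Configure a synthetic multi-environment trial
#'
#' Builds the configuration object consumed by [simulate_panel()] and
#' [simulate_genotypes()]. Defaults emulate a diverse-accession soybean panel:
#' 292 accessions grown in 6 environments in an alpha-lattice design with
#' 2 replicates of 30 incomplete blocks each, hyperspectral canopy
#' reflectance on a 1-nm grid from 350 to 2500 nm at two growth stages
#' (S1 flowering, S2 pod set), and a dense biallelic SNP panel. Genetic
#' signal in the spectrum is concentrated in the red-edge (700-850 nm) and
#' a shortwave-infrared window (2030-2119 nm), where band-level genetic
#' correlations with seed yield are strongest.
#'
#' Yield is generated plot-wise as
#' \deqn{y = \mu + E + R + B(R) + G + G{\times}E + \varepsilon}
#' with independent normal effects. The genotypic variance is derived from
#' `h2_yield` so that the entry-mean repeatability
#' \eqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{gxe}/e + \sigma^2_\varepsilon/(re))}
#' equals `h2_yield` exactly under the configured design.
#'
#' @param n_genotypes Number of accessions.
#' @param n_environments Number of environments (location-year combinations).
#' @param n_reps Replicates per environment.
#' @param n_blocks_per_rep Incomplete blocks per replicate.
#' @param n_snps Number of biallelic SNP markers.
#' @param n_causal Number of causal markers behind the yield genetic value.
#' @param band_range Wavelength interval (nm) covered by the spectrometer.
#' @param band_step Grid step in nm; 1 reproduces the full-resolution
#'   instrument, larger steps give reduced grids for fast experimentation.
#' @param informative_regions Data frame with columns `start`, `end` (nm) and
#'   `rg`, the target genetic correlation between band reflectance and yield
#'   inside each region.
#' @param h2_yield Entry-mean repeatability of seed yield, in `[0, 1]`.
#' @param mean_yield Grand mean seed yield (kg/ha at 13% moisture).
#' @param var_env,var_gxe,var_rep,var_block,var_resid Variance components of
#'   the yield model (kg^2/ha^2); all must be nonnegative.
#' @param frac_low_stand Fraction of plots planted with degraded emergence
#'   (very low stand counts) so emergence filters are exercised.
#' @param frac_shatter Fraction of plots given pre-harvest shatter scores of
#'   4 or 5.
#' @param n_sparse_environments Number of trailing environments without
#'   phenomic (spectral and canopy) data; yield is still recorded there.
#'   Mirrors trials where only a subset of environments has complete sensor
#'   coverage.
#' @param maf_range Range from which ancestral allele frequencies are drawn
#'   (uniform).
#' @param seed Integer seed; the same seed reproduces the dataset bit for bit.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_genotypes = 40, n_environments = 2, n_blocks_per_rep = 5,
#'                   n_snps = 100, band_range = c(600, 900), band_step = 10,
#'                   n_sparse_environments = 0, seed = 7)
sim_config <- function(n_genotypes = 292,
                       n_environments = 6,
                       n_reps = 2,
                       n_blocks_per_rep = 30,
                       n_snps = 35000,
                       n_causal = 200,
                       band_range = c(350, 2500),
                       band_step = 1,
                       informative_regions = data.frame(
                         start = c(700, 2030),
                         end   = c(850, 2119),
                         rg    = c(-0.70, -0.80)
                       ),
                       h2_yield = 0.5,
                       mean_yield = 2500,
                       var_env = 5000,
                       var_gxe = 60000,
                       var_rep = 5000,
                       var_block = 2500,
                       var_resid = 60000,
                       frac_low_stand = 0.01,
                       frac_shatter = 0.01,
                       n_sparse_environments = if (n_environments >= 6) 2 else 0,
                       maf_range = c(0.05, 0.95),
                       seed = 1) {
  counts <- c(n_genotypes = n_genotypes, n_environments = n_environments,
              n_reps = n_reps, n_blocks_per_rep = n_blocks_per_rep,
              n_snps = n_snps, n_causal = n_causal)
  if (any(counts < 1))
    abort(paste0("sim_config: counts must be positive; offending: ",
                 paste(names(counts)[counts < 1], collapse = ", ")),
          class = "phenosel_config_error")
  vars <- c(var_env = var_env, var_gxe = var_gxe, var_rep = var_rep,
            var_block = var_block, var_resid = var_resid)
  if (any(vars < 0))
    abort("sim_config: variance components must be nonnegative",
          class = "phenosel_config_error")
  if (h2_yield < 0 || h2_yield > 1)
    abort("sim_config: h2_yield must lie in [0, 1]",
          class = "phenosel_config_error")
  stopifnot(length(band_range) == 2, band_range[1] < band_range[2],
            band_step >= 1)
  ir <- as.data.frame(informative_regions)
  if (nrow(ir) > 0) {
    if (!all(c("start", "end", "rg") %in% names(ir)))
      abort("informative_regions needs columns start, end, rg",
            class = "phenosel_config_error")
    if (any(ir$start < band_range[1]) || any(ir$end > band_range[2]))
      abort("informative_regions must lie within band_range",
            class = "phenosel_config_error")
    if (any(abs(ir$rg) > 1))
      abort("informative_regions: |rg| must be <= 1",
            class = "phenosel_config_error")
  }
  if (n_sparse_environments >= n_environments)
    abort("n_sparse_environments must leave at least one complete environment",
          class = "phenosel_config_error")
  if (n_causal > n_snps)
    abort("n_causal cannot exceed n_snps", class = "phenosel_config_error")

  # genotypic variance implied by the target entry-mean repeatability
  noise_mean <- var_gxe / n_environments + var_resid / (n_reps * n_environments)
  if (h2_yield == 1 && noise_mean > 0)
    abort("h2_yield = 1 requires var_gxe = var_resid = 0",
          class = "phenosel_config_error")
  var_g <- if (h2_yield >= 1) 1 else h2_yield / (1 - h2_yield) * noise_mean

  structure(list(
    n_genotypes = as.integer(n_genotypes),
    n_environments = as.integer(n_environments),
    n_reps = as.integer(n_reps),
    n_blocks_per_rep = as.integer(n_blocks_per_rep),
    n_snps = as.integer(n_snps),
    n_causal = as.integer(n_causal),
    band_range = band_range,
    band_step = band_step,
    informative_regions = ir,
    h2_yield = h2_yield,
    mean_yield = mean_yield,
    var_g = var_g,
    var_env = var_env, var_gxe = var_gxe, var_rep = var_rep,
    var_block = var_block, var_resid = var_resid,
    frac_low_stand = frac_low_stand,
    frac_shatter = frac_shatter,
    n_sparse_environments = as.integer(n_sparse_environments),
    maf_range = maf_range,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genotypes x %d environments x %d reps, %d blocks/rep\n",
              x$n_genotypes, x$n_environments, x$n_reps, x$n_blocks_per_rep))
  cat(sprintf("  spectra: %d-%d nm (step %g), %d informative region(s)\n",
              x$band_range[1], x$band_range[2], x$band_step,
              nrow(x$informative_regions)))
  cat(sprintf("  SNPs: %d (%d causal), h2_yield = %.2f, seed = %d\n",
              x$n_snps, x$n_causal, x$h2_yield, x$seed))
  invisible(x)
}

#' Wavelength grid of a configuration
#' @param config A [sim_config()] object.
#' @return Numeric vector of band-center wavelengths in nm.
#' @export
band_grid <- function(config) {
  seq(config$band_range[1], config$band_range[2], by = config$band_step)
}
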