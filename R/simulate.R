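#' Simulate a genotype-by-SNP marker matrix
#'
#' Draws per-marker ancestral allele frequencies uniformly on
#' `config$maf_range` and genotype codes as binomial(2, p) counts of the
#' alternate allele, the standard additive coding \{0, 1, 2\}.
#'
#' @param config A [sim_config()] object.
#' @return Integer matrix (`n_genotypes` x `n_snps`) with genotype and marker
#'   dimnames; codes 0/1/2.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_g <- config$n_genotypes
  n_m <- config$n_snps
  p <- runif(n_m, config$maf_range[1], config$maf_range[2])
  codes <- matrix(rbinom(n_g * n_m, 2L, rep(p, each = n_g)), nrow = n_g)
  dimnames(codes) <- list(.geno_ids(n_g), .snp_ids(n_m))
  storage.mode(codes) <- "integer"
  attr(codes, "allele_freq") <- setNames(p, colnames(codes))
  codes
}

.geno_ids <- function(n) sprintf("G%04d", seq_len(n))
.snp_ids <- function(n) sprintf("snp%06d", seq_len(n))
.env_ids <- function(n) sprintf("E%02d", seq_len(n))

# running-mean smoothing of each row across columns, edge-padded
.smooth_rows <- function(m, w) {
  if (w <= 1 || ncol(m) < 3) return(m)
  half <- floor(w / 2)
  w <- 2L * half + 1L
  padded <- cbind(m[, rep(1, half), drop = FALSE], m,
                  m[, rep(ncol(m), half), drop = FALSE])
  out <- t(stats::filter(t(padded), rep(1 / w, w), sides = 2))
  out[, (half + 1):(half + ncol(m)), drop = FALSE]
}

# smooth standard-normal matrix, re-standardised column-wise
.smooth_noise <- function(n_row, n_col, w) {
  z <- matrix(rnorm(n_row * n_col), n_row, n_col)
  z <- .smooth_rows(z, w)
  if (n_row > 1) {
    mu <- colMeans(z)
    sdv <- apply(z, 2, sd)
    sdv[sdv < 1e-12] <- 1
    z <- sweep(sweep(z, 2, mu), 2, sdv, "/")
  }
  z
}

# vegetation-like baseline reflectance curve over wavelength (nm)
.baseline_spectrum <- function(wl) {
  anchors_x <- c(350, 500, 550, 620, 680, 705, 750, 900, 1100, 1300, 1450,
                 1660, 1800, 1940, 2100, 2250, 2400, 2500)
  anchors_y <- c(0.04, 0.05, 0.10, 0.07, 0.05, 0.15, 0.40, 0.44, 0.43, 0.42,
                 0.26, 0.32, 0.30, 0.12, 0.20, 0.18, 0.10, 0.08)
  f <- splinefun(anchors_x, anchors_y, method = "monoH.FC")
  f(wl)
}

# target band-level genetic correlation with yield and repeatability profile;
# within an informative region the correlation follows a smooth bump peaking
# at the region centre (real correlation profiles taper at region edges,
# which is what lets band-difference indices retain signal)
.band_truth <- function(config, wl) {
  rg <- rep(0, length(wl))
  h2 <- 0.15 + 0.25 * (0.5 + 0.5 * sin(2 * pi * (wl - 350) / 900))
  ir <- config$informative_regions
  if (nrow(ir) > 0) {
    for (k in seq_len(nrow(ir))) {
      idx <- which(wl >= ir$start[k] & wl <= ir$end[k])
      if (length(idx) == 0) next
      x <- (wl[idx] - ir$start[k]) / max(ir$end[k] - ir$start[k], 1)
      shape <- 0.35 + 0.65 * sin(pi * x)
      rg[idx] <- ir$rg[k] * shape
      h2[idx] <- pmax(h2[idx], 0.3 + 0.5 * shape)
    }
  }
  list(rg = rg, h2 = h2)
}

#' Simulate a full phenomic-assisted selection trial
#'
#' Generates, under one seed, every dataset the pipeline consumes: plot-level
#' yield records in an alpha-lattice design (environments, replicates,
#' incomplete blocks, data-collection passes), two-scan canopy reflectance
#' spectra at growth stages S1 and S2, canopy area and temperature traits,
#' a SNP matrix, and a ground-truth record for parameter-recovery tests.
#'
#' Seed yield per plot follows the additive model
#' \eqn{y = \mu + E + R + B(R) + G + G{\times}E + \varepsilon} with genetic
#' values additive in a random subset of causal markers. Band reflectance is
#' a smooth vegetation baseline plus a genotype-level genetic deviation whose
#' correlation with the yield genetic value equals the configured target in
#' each informative region (0 elsewhere), plus environment, genotype-by-
#' environment and residual noise. Band G-by-E deviations are correlated with
#' yield G-by-E through the same target, so environment-specific spectra are
#' informative about environment-specific yield ranks. A configurable
#' fraction of plots receives degraded stand counts and shatter scores >= 4
#' so that the plot-quality filters are exercised.
#'
#' The trailing `n_sparse_environments` environments carry yield but no
#' phenomic data, mirroring trials with incomplete sensor coverage.
#'
#' @param config A [sim_config()] object.
#' @return A `phenosel_sim` list with elements `plots` (tibble), `spectra`
#'   (list with per-stage tibbles, two scans per plot), `canopy` (tibble),
#'   `snps` (matrix), `truth` (list), and `config`.
#' @export
#' @examples
#' sim <- simulate_panel(sim_config(n_genotypes = 30, n_environments = 2,
#'   n_blocks_per_rep = 5, n_snps = 80, band_range = c(600, 800),
#'   band_step = 20, n_sparse_environments = 0, seed = 3))
#' dim(sim$plots)
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  snps <- simulate_genotypes(config)  # seeds the stream; draws continue below

  n_g <- config$n_genotypes
  n_e <- config$n_environments
  n_r <- config$n_reps
  n_b <- config$n_blocks_per_rep
  genos <- rownames(snps)
  envs <- .env_ids(n_e)
  complete_envs <- envs[seq_len(n_e - config$n_sparse_environments)]

  ## --- genetic values additive in causal markers -------------------------
  causal <- sort(sample.int(config$n_snps, config$n_causal))
  beta <- rnorm(config$n_causal)
  p <- attr(snps, "allele_freq")[causal]
  W <- sweep(snps[, causal, drop = FALSE], 2, 2 * p)
  g_raw <- drop(W %*% beta)
  g_raw <- g_raw - mean(g_raw)
  sd_raw <- sd(g_raw)
  g <- if (sd_raw < 1e-12) rep(0, n_g) else g_raw / sd_raw * sqrt(config$var_g)
  s <- if (sd(g) < 1e-12) rep(0, n_g) else as.numeric(scale(g))

  ## --- design + yield ----------------------------------------------------
  env_eff <- rnorm(n_e, 0, sqrt(config$var_env))
  gxe <- matrix(rnorm(n_g * n_e, 0, sqrt(config$var_gxe)), n_g, n_e,
                dimnames = list(genos, envs))
  t_std <- if (config$var_gxe > 0) gxe / sqrt(config$var_gxe) else gxe

  plots_per_pass <- 24L
  rows <- vector("list", n_e * n_r)
  idx <- 0L
  for (i in seq_len(n_e)) {
    plot_counter <- 0L
    for (j in seq_len(n_r)) {
      idx <- idx + 1L
      rep_eff <- rnorm(1, 0, sqrt(config$var_rep))
      ord <- sample.int(n_g)
      block_of <- rep(seq_len(n_b), length.out = n_g)[order(ord)]
      block_eff <- rnorm(n_b, 0, sqrt(config$var_block))
      eps <- rnorm(n_g, 0, sqrt(config$var_resid))
      y13 <- config$mean_yield + env_eff[i] + rep_eff + block_eff[block_of] +
        g + gxe[, i] + eps
      y13 <- pmax(y13, 0)
      plot_seq <- plot_counter + seq_len(n_g)
      plot_counter <- plot_counter + n_g
      rows[[idx]] <- tibble(
        environment = envs[i],
        replicate = sprintf("R%d", j),
        block = sprintf("B%02d", block_of),
        pass = sprintf("%s_P%02d", envs[i], ceiling(plot_seq / plots_per_pass)),
        plot_id = sprintf("%s_%04d", envs[i], plot_seq),
        genotype = genos,
        yield13 = y13
      )
    }
  }
  plots <- list_rbind(rows)
  n_plots <- nrow(plots)

  moisture <- pmin(pmax(rnorm(n_plots, 0.13, 0.015), 0.06), 0.25)
  stand <- rpois(n_plots, 30)
  shatter <- sample(1:3, n_plots, replace = TRUE, prob = c(0.75, 0.20, 0.05))
  n_low <- round(config$frac_low_stand * n_plots)
  n_shat <- round(config$frac_shatter * n_plots)
  degraded <- sample.int(n_plots, n_low + n_shat)
  if (n_low > 0) stand[degraded[seq_len(n_low)]] <- sample(0:4, n_low, TRUE)
  if (n_shat > 0)
    shatter[degraded[n_low + seq_len(n_shat)]] <- sample(4:5, n_shat, TRUE)

  plots <- plots |>
    mutate(
      stand_count = stand,
      shatter_score = shatter,
      moisture = moisture,
      seed_yield = .data$yield13 * (1 - 0.13) / (1 - moisture)
    ) |>
    select("environment", "replicate", "block", "pass", "plot_id", "genotype",
           "stand_count", "shatter_score", "moisture", "seed_yield")

  ## --- spectra -----------------------------------------------------------
  wl <- band_grid(config)
  nb <- length(wl)
  truth_bands <- .band_truth(config, wl)
  rho <- truth_bands$rg
  e_c <- length(complete_envs)
  var_eps_b <- 0.010^2
  var_gxe_b <- 0.012^2
  sd_scan <- 0.004
  # environment- and region-specific coupling of spectral G-by-E to yield
  # G-by-E: the relative weighting of informative spectral regions differs
  # across environments (reaction-norm heterogeneity), so a model trained
  # without the target environment weights regions suboptimally there
  n_regions <- max(1L, nrow(config$informative_regions))
  w_env <- matrix(runif(n_e * n_regions), n_e, n_regions,
                  dimnames = list(envs, NULL))
  # per-environment expression strength of each informative region: the
  # physiological association between a spectral region and yield is not
  # equally expressed in every environment (stress- and stage-dependent),
  # so which regions carry signal varies across environments
  a_env <- matrix(runif(n_e * n_regions, 0.4, 1), n_e, n_regions,
                  dimnames = list(envs, NULL))
  # normalise expression to mean 1 over the phenomics-complete environments,
  # so planted repeatability and correlation targets hold on average while
  # environments still differ in relative expression
  a_env <- sweep(a_env, 2,
                 colMeans(a_env[seq_len(n_e - config$n_sparse_environments),
                                , drop = FALSE]), "/")
  region_of <- rep(0L, nb)
  ir <- config$informative_regions
  if (nrow(ir) > 0)
    for (k in seq_len(nrow(ir)))
      region_of[wl >= ir$start[k] & wl <= ir$end[k]] <- k
  var_g_b <- truth_bands$h2 / (1 - truth_bands$h2) *
    (var_gxe_b / e_c + var_eps_b / (n_r * e_c))
  sd_g_b <- sqrt(var_g_b)
  smooth_w <- max(3L, round(30 / config$band_step))
  base <- .baseline_spectrum(wl)

  stage_offsets <- c(S1 = 0, S2 = 0.015)
  spectra <- list()
  canopy_rows <- list()
  rho_ca <- c(S1 = 0.33, S2 = 0.25)
  rho_ct <- -0.44
  env_ca <- rnorm(n_e, 0, 0.03)
  env_ct <- rnorm(n_e, 0, 1.0)
  w_ca <- list(S1 = rnorm(n_g), S2 = rnorm(n_g))
  v_ct <- rnorm(n_g)
  # canopy growth also shows G-by-E, partially aligned with yield G-by-E
  # (per-environment coupling, as for the spectral regions)
  u_can <- matrix(runif(n_e * 3), n_e, 3,
                  dimnames = list(envs, c("CA_S1", "CA_S2", "CT_S2")))

  for (stage in c("S1", "S2")) {
    Z <- .smooth_noise(n_g, nb, smooth_w)
    gamma <- sweep(outer(s, rho) + sweep(Z, 2, sqrt(pmax(0, 1 - rho^2)), "*"),
                   2, sd_g_b, "*")
    env_band <- .smooth_rows(matrix(rnorm(e_c * nb, 0, 1), e_c, nb), smooth_w) * 0.03
    stage_rows <- vector("list", e_c * 2L)
    k <- 0L
    for (ei in seq_along(complete_envs)) {
      e_name <- complete_envs[ei]
      env_plots <- plots |> filter(.data$environment == e_name)
      gi <- match(env_plots$genotype, genos)
      U <- .smooth_noise(n_g, nb, smooth_w)
      coupling <- ifelse(region_of > 0,
                         w_env[e_name, pmax(region_of, 1L)], 0)
      rho_e <- rho * coupling
      gxe_band <- sweep(outer(t_std[, e_name], rho_e) +
                          sweep(U, 2, sqrt(pmax(0, 1 - rho_e^2)), "*"),
                        2, sqrt(var_gxe_b), "*")
      a_vec <- ifelse(region_of > 0,
                      a_env[e_name, pmax(region_of, 1L)], 1)
      signal <- sweep(gamma[gi, , drop = FALSE] +
                        gxe_band[gi, , drop = FALSE], 2, a_vec, "*")
      plot_val <- matrix(rep(base + stage_offsets[[stage]], each = nrow(env_plots)),
                         nrow(env_plots), nb) +
        matrix(rep(env_band[ei, ], each = nrow(env_plots)), nrow(env_plots), nb) +
        signal +
        matrix(rnorm(nrow(env_plots) * nb, 0, sqrt(var_eps_b)),
               nrow(env_plots), nb)
      for (scan in 1:2) {
        k <- k + 1L
        vals <- plot_val + matrix(rnorm(length(plot_val), 0, sd_scan),
                                  nrow(plot_val), nb)
        vals <- pmin(pmax(vals, 0.001), 0.999)
        colnames(vals) <- as.character(wl)
        stage_rows[[k]] <- bind_cols(
          tibble(environment = env_plots$environment,
                 plot_id = env_plots$plot_id,
                 scan = scan),
          as_tibble(vals)
        )
      }
    }
    spectra[[stage]] <- list_rbind(stage_rows) |>
      arrange(.data$environment, .data$plot_id, .data$scan)
  }

  ## --- canopy traits -----------------------------------------------------
  for (ei in seq_along(complete_envs)) {
    e_name <- complete_envs[ei]
    e_idx <- match(e_name, envs)
    env_plots <- plots |> filter(.data$environment == e_name)
    gi <- match(env_plots$genotype, genos)
    np <- nrow(env_plots)
    t_e <- t_std[, e_name]
    gxe_ca1 <- 0.06 * (u_can[e_name, "CA_S1"] * t_e +
                         sqrt(1 - u_can[e_name, "CA_S1"]^2) * rnorm(n_g))
    gxe_ca2 <- 0.06 * (u_can[e_name, "CA_S2"] * t_e +
                         sqrt(1 - u_can[e_name, "CA_S2"]^2) * rnorm(n_g))
    gxe_ct <- -0.9 * (u_can[e_name, "CT_S2"] * t_e +
                        sqrt(1 - u_can[e_name, "CT_S2"]^2) * rnorm(n_g))
    ca1 <- 0.55 + 0.10 * (rho_ca[["S1"]] * s[gi] +
                            sqrt(1 - rho_ca[["S1"]]^2) * w_ca$S1[gi]) +
      gxe_ca1[gi] + env_ca[e_idx] + rnorm(np, 0, 0.04)
    ca2 <- 0.60 + 0.10 * (rho_ca[["S2"]] * s[gi] +
                            sqrt(1 - rho_ca[["S2"]]^2) * w_ca$S2[gi]) +
      gxe_ca2[gi] + env_ca[e_idx] + rnorm(np, 0, 0.04)
    passes <- unique(env_plots$pass)
    pass_off <- setNames(rnorm(length(passes), 0, 1.5), passes)
    ct2 <- 28 + env_ct[e_idx] + pass_off[env_plots$pass] +
      1.2 * (rho_ct * s[gi] + sqrt(1 - rho_ct^2) * v_ct[gi]) +
      gxe_ct[gi] + rnorm(np, 0, 0.5)
    canopy_rows[[ei]] <- tibble(
      environment = env_plots$environment,
      plot_id = env_plots$plot_id,
      pass = env_plots$pass,
      CA_S1 = pmin(pmax(ca1, 0.01), 0.99),
      CA_S2 = pmin(pmax(ca2, 0.01), 0.99),
      CT_S2 = as.numeric(ct2)
    )
  }
  canopy <- list_rbind(canopy_rows)

  # realized entry-mean repeatability accounting for the per-environment
  # expression strength of informative regions (attenuation scales the
  # genotype-level signal; its environment-to-environment spread moves
  # genetic variance into the G-by-E component)
  a_complete <- a_env[complete_envs, , drop = FALSE]
  am <- colMeans(a_complete)
  m2 <- colMeans(a_complete^2)
  am_b <- ifelse(region_of > 0, am[pmax(region_of, 1L)], 1)
  m2_b <- ifelse(region_of > 0, m2[pmax(region_of, 1L)], 1)
  h2_real <- repeatability(am_b^2 * var_g_b,
                           (m2_b - am_b^2) * var_g_b + m2_b * var_gxe_b,
                           var_eps_b + sd_scan^2 / 2, n_r, e_c)

  truth <- list(
    true_genetic_values = tibble(genotype = genos, value = g),
    true_band_rg = tibble(wavelength = wl, rg = rho),
    true_band_h2 = tibble(wavelength = wl, h2 = h2_real),
    true_h2_snp = config$h2_yield,
    variances = list(var_g = config$var_g, var_env = config$var_env,
                     var_gxe = config$var_gxe, var_rep = config$var_rep,
                     var_block = config$var_block,
                     var_resid = config$var_resid),
    causal_snps = colnames(snps)[causal],
    yield_gxe = gxe,
    env_coupling = w_env,
    env_expression = a_env,
    complete_environments = complete_envs
  )

  structure(list(plots = plots, spectra = spectra, canopy = canopy,
                 snps = snps, truth = truth, config = config),
            class = "phenosel_sim")
}

#' @export
print.phenosel_sim <- function(x, ...) {
  cat("<phenosel_sim>\n")
  cat(sprintf("  plots: %d rows (%d genotypes, %d environments)\n",
              nrow(x$plots), x$config$n_genotypes, x$config$n_environments))
  cat(sprintf("  spectra: %d bands x 2 stages, complete in %d environment(s)\n",
              length(band_grid(x$config)),
              length(x$truth$complete_environments)))
  cat(sprintf("  snps: %d x %d\n", nrow(x$snps), ncol(x$snps)))
  invisible(x)
}
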