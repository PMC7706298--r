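test_that("balanced one-random-term BLUPs match the closed-form shrinkage", {
  set.seed(21)
  n_g <- 5; n_rep <- 3
  g <- rnorm(n_g, 0, 2)
  d <- tidyr::expand_grid(genotype = sprintf("g%d", 1:n_g), rep = 1:n_rep) |>
    dplyr::mutate(y = g[as.integer(sub("g", "", genotype))] +
                    rnorm(dplyr::n()))
  fit <- fit_mixed_model(d, "y", random = "genotype")
  vc <- setNames(fit$vc$variance, fit$vc$term)
  gm <- tapply(d$y, d$genotype, mean)
  k <- n_rep * vc[["genotype"]] / (n_rep * vc[["genotype"]] + vc[["residual"]])
  oracle <- k * (gm - mean(d$y))
  got <- genotype_blups(fit)
  expect_equal(got$blup, as.numeric(oracle[got$genotype]), tolerance = 1e-6)
  # shrinkage bound
  expect_true(all(abs(got$blup) <= abs(gm[got$genotype] - mean(d$y)) + 1e-10))
})

test_that("a pure-noise response yields near-zero genotype BLUPs", {
  set.seed(5)
  d <- tidyr::expand_grid(genotype = sprintf("g%d", 1:10), rep = 1:4) |>
    dplyr::mutate(y = rnorm(dplyr::n()))
  fit <- fit_mixed_model(d, "y", random = "genotype")
  gm <- tapply(d$y, d$genotype, mean)
  b <- genotype_blups(fit)
  expect_true(all(abs(b$blup) <= abs(gm[b$genotype] - mean(d$y)) + 1e-10))
  expect_lt(mean(abs(b$blup)), mean(abs(gm - mean(d$y))))
})

test_that("more residual noise means more shrinkage", {
  set.seed(31)
  n_g <- 40; g <- rnorm(n_g)
  base <- tidyr::expand_grid(genotype = sprintf("g%02d", 1:n_g), rep = 1:3)
  mean_abs <- vapply(c(0.5, 4), function(s) {
    d <- dplyr::mutate(base, y = g[as.integer(sub("g", "", genotype))] +
                         rnorm(dplyr::n(), 0, s))
    mean(abs(genotype_blups(fit_mixed_model(d, "y", random = "genotype"))$blup))
  }, numeric(1))
  expect_gt(mean_abs[1], mean_abs[2])
})

test_that("variance components of the full trial model are recoverable", {
  cfg <- small_config(n_genotypes = 120, n_environments = 4,
                      n_sparse_environments = 0, h2_yield = 0.5,
                      band_range = c(700, 710), band_step = 10,
                      informative_regions = data.frame(start = 700, end = 710,
                                                       rg = -0.7))
  sim <- simulate_panel(cfg)
  d <- dplyr::mutate(sim$plots,
                     y13 = adjust_moisture(seed_yield, moisture))
  fit <- fit_mixed_model(d, "y13")
  vc <- setNames(fit$vc$variance, fit$vc$term)
  expect_lt(abs(vc[["residual"]] - cfg$var_resid) / cfg$var_resid, 0.4)
  expect_lt(abs(vc[["genotype"]] - cfg$var_g) / cfg$var_g, 0.8)
  expect_true(fit$converged)
})

test_that("studentized-residual pass flags exactly the planted outlier", {
  set.seed(7)
  d <- tidyr::expand_grid(genotype = sprintf("g%02d", 1:20), rep = 1:3) |>
    dplyr::mutate(y = rnorm(dplyr::n(), 0, 1))
  d$y[13] <- d$y[13] + 10
  fit <- fit_mixed_model(d, "y", random = "genotype")
  res <- remove_outliers_studentized(fit, threshold = 3)
  expect_equal(nrow(res$flagged), 1)
  expect_equal(res$clean$y, d$y[-13])

  res_inf <- remove_outliers_studentized(fit, threshold = Inf)
  expect_equal(nrow(res_inf$flagged), 0)
  expect_identical(res_inf$fit, fit)
})

test_that("by-environment BLUPs are symmetric across identical environments", {
  set.seed(11)
  one <- tidyr::expand_grid(replicate = c("R1", "R2"),
                            genotype = sprintf("g%02d", 1:15)) |>
    dplyr::mutate(block = rep(sprintf("B%d", 1:3), length.out = dplyr::n()),
                  y = rnorm(dplyr::n()))
  two <- dplyr::bind_rows(dplyr::mutate(one, environment = "E1"),
                          dplyr::mutate(one, environment = "E2"))
  b <- suppressMessages(blups_method1(two, "y"))
  expect_equal(b$blup[b$environment == "E1"], b$blup[b$environment == "E2"],
               tolerance = 1e-8)
  expect_equal(nrow(b), 2 * 15)
  expect_error(blups_method1(dplyr::mutate(two, replicate = "R1"), "y"),
               class = "phenosel_validation_error")
})

test_that("across-environment BLUPs reduce to the by-environment model with one environment", {
  sim <- simulate_panel(tiny_config(n_genotypes = 40))
  d <- dplyr::filter(sim$plots, environment == "E01") |>
    dplyr::mutate(y13 = adjust_moisture(seed_yield, moisture))
  b1 <- suppressMessages(blups_method1(d, "y13"))
  b2 <- suppressMessages(blups_method2(d, "y13"))
  expect_equal(b2$blup, b1$blup[match(b2$genotype, b1$genotype)],
               tolerance = 1e-6)
})

test_that("unbalanced data still yields BLUPs for every observed genotype", {
  sim <- simulate_panel(tiny_config(n_genotypes = 40))
  d <- dplyr::mutate(sim$plots,
                     y13 = adjust_moisture(seed_yield, moisture)) |>
    dplyr::filter(!(genotype %in% sprintf("G%04d", 1:10) &
                      environment == "E02"))
  b <- suppressMessages(blups_method2(d, "y13"))
  expect_equal(nrow(b), 40)
  expect_true(all(is.finite(b$blup)))
})

test_that("methods agree when genotype-by-environment variance is absent", {
  cfg <- tiny_config(n_genotypes = 80, n_environments = 2, var_gxe = 0,
                     h2_yield = 0.95, seed = 3)
  sim <- simulate_panel(cfg)
  d <- dplyr::mutate(sim$plots,
                     y13 = adjust_moisture(seed_yield, moisture))
  b1 <- suppressMessages(blups_method1(d, "y13"))
  b2 <- suppressMessages(blups_method2(d, "y13"))
  merged <- dplyr::inner_join(b1, b2, by = "genotype",
                              suffix = c("_m1", "_m2"))
  expect_gt(cor(merged$blup_m1, merged$blup_m2), 0.85)
})

test_that("method divergence grows with genotype-by-environment variance", {
  rank_cor <- vapply(c(0, 15000, 60000), function(v) {
    cfg <- tiny_config(n_genotypes = 60, n_environments = 3, var_gxe = v,
                       h2_yield = 0.7, seed = 17)
    sim <- simulate_panel(cfg)
    d <- dplyr::mutate(sim$plots,
                       y13 = adjust_moisture(seed_yield, moisture))
    b1 <- suppressMessages(blups_method1(d, "y13"))
    b2 <- suppressMessages(blups_method2(d, "y13"))
    m <- dplyr::inner_join(b1, b2, by = "genotype", suffix = c("_1", "_2"))
    cor(m$blup_1, m$blup_2, method = "spearman")
  }, numeric(1))
  expect_true(rank_cor[1] > rank_cor[3])
})

test_that("tidy and glance expose the fit in broom style", {
  set.seed(2)
  d <- tidyr::expand_grid(genotype = sprintf("g%d", 1:8), rep = 1:3) |>
    dplyr::mutate(y = rnorm(dplyr::n()))
  fit <- fit_mixed_model(d, "y", random = "genotype")
  td <- tidy(fit)
  expect_named(td, c("term", "variance"))
  expect_true("residual" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$n_obs, 24)
})
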