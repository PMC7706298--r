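test_that("emergence filter removes plots far below the first quartile", {
  counts <- c(2, 3, 9, 9, 9, 9, 12, 12, 12, 12)
  plots <- tibble::tibble(environment = "E01",
                          plot_id = sprintf("p%02d", seq_along(counts)),
                          stand_count = counts)
  # oracle: linear-interpolation quartiles of this environment
  q1 <- quantile(counts, 0.25, type = 7)
  thr <- q1 - 2 * IQR(counts, type = 7)
  expect_equal(unname(thr), 3)
  res <- filter_low_emergence(plots)
  expect_equal(res$removed$plot_id, "p01")      # 2 < 3, strictly below
  expect_true("p02" %in% res$retained$plot_id)  # 3 is not strictly below

  same <- tibble::tibble(environment = "E01", plot_id = c("a", "b", "c"),
                         stand_count = c(30, 30, 30))
  expect_equal(nrow(filter_low_emergence(same)$removed), 0)

  expect_error(filter_low_emergence(
    tibble::tibble(environment = "E01", plot_id = "a",
                   stand_count = NA_real_)),
    class = "phenosel_validation_error")
})

test_that("quartiles are computed per environment, not pooled", {
  plots <- tibble::tibble(
    environment = rep(c("A", "B"), each = 6),
    plot_id = sprintf("p%02d", 1:12),
    stand_count = c(30, 30, 30, 31, 31, 5,     # 5 is low within A
                    5, 5, 5, 6, 6, 6))          # all low-ish, none removed in B
  res <- filter_low_emergence(plots)
  expect_equal(res$removed$environment, "A")
})

test_that("shatter filter drops yield at score >= 4 only", {
  plots <- tibble::tibble(environment = "E", plot_id = letters[1:4],
                          shatter_score = c(1, 3, 4, 5))
  res <- filter_shattered(plots)
  expect_equal(res$removed$plot_id, c("c", "d"))
  expect_equal(res$retained$plot_id, c("a", "b"))
  none <- filter_shattered(tibble::tibble(environment = "E",
                                          plot_id = "x", shatter_score = 1))
  expect_equal(nrow(none$removed), 0)
})

test_that("moisture adjustment preserves dry matter at the 13% basis", {
  expect_equal(adjust_moisture(2000, 0.13), 2000)
  expect_equal(adjust_moisture(1000, 0.10), 1034.48, tolerance = 1e-4)
  expect_equal(adjust_moisture(1000, 0.20), 919.54, tolerance = 1e-4)
  expect_error(adjust_moisture(1000, 1.0),
               class = "phenosel_validation_error")
})

test_that("pass normalization removes additive ambient drift", {
  d <- tibble::tibble(pass = c("p1", "p1"), ct = c(30, 32))
  out <- normalize_ct_by_pass(d, ct, pass)
  expect_equal(out$ct, c(-1, 1))

  two <- tibble::tibble(pass = rep(c("p1", "p2"), each = 3),
                        ct = c(28, 29, 30, 33, 34, 35))  # +5 offset in p2
  out2 <- normalize_ct_by_pass(two, ct, pass)
  expect_equal(out2$ct[1:3], out2$ct[4:6])

  single <- tibble::tibble(pass = "p1", ct = 28)
  expect_warning(out3 <- normalize_ct_by_pass(single, ct, pass), "single")
  expect_equal(out3$ct, 0)
})

test_that("scan averaging is the per-band arithmetic mean with NA fallback", {
  sp <- tibble::tibble(environment = "E", plot_id = c("p1", "p1"),
                       scan = 1:2, `700` = c(0.2, 0.4), `710` = c(0.3, 0.3))
  out <- average_plot_reflectance(sp)
  expect_equal(out$`700`, 0.3)
  expect_equal(out$`710`, 0.3)

  sp$`700`[2] <- NA
  expect_warning(out2 <- average_plot_reflectance(sp), "single-scan")
  expect_equal(out2$`700`, 0.2)
})

test_that("repeatability follows the entry-mean formula and its limits", {
  expect_equal(repeatability(2, 2, 4, r = 2, e = 2), 0.5)
  expect_equal(repeatability(3, 0, 0, r = 2, e = 4), 1)
  expect_equal(repeatability(0, 1, 1, r = 2, e = 4), 0)
  expect_equal(repeatability(0, 0, 0, r = 2, e = 4), 0)
  expect_equal(repeatability(-0.5, 1, 1, r = 2, e = 2), 0)  # truncation
  # monotone in replicates and environments for fixed components
  h <- function(r, e) repeatability(1, 1, 2, r, e)
  grid <- expand.grid(r = 1:4, e = 1:4)
  for (i in seq_len(nrow(grid) - 1)) {
    expect_lte(h(grid$r[i], grid$e[i]), h(grid$r[i] + 1, grid$e[i]) + 1e-12)
    expect_lte(h(grid$r[i], grid$e[i]), h(grid$r[i], grid$e[i] + 1) + 1e-12)
  }
})

test_that("band repeatability estimation needs several environments", {
  sim <- simulate_panel(tiny_config())
  sp <- suppressWarnings(average_plot_reflectance(sim$spectra$S1))
  d <- dplyr::inner_join(
    sim$plots[, c("environment", "replicate", "block", "plot_id",
                  "genotype")], sp, by = c("environment", "plot_id"))
  est <- suppressMessages(
    estimate_band_repeatability(d, bands = c("600", "700")))
  expect_equal(nrow(est), 2)
  expect_true(all(est$H2 >= 0 & est$H2 <= 1))
  expect_error(
    estimate_band_repeatability(dplyr::filter(d, environment == "E01")),
    class = "phenosel_validation_error")
})

test_that("repeatability band filter is strict at the threshold", {
  est <- tibble::tibble(band = c("a", "b", "c"), H2 = c(0.29, 0.30, 0.31))
  kept <- filter_bands_by_repeatability(est, 0.3)
  expect_equal(as.character(kept), c("b", "c"))
  expect_equal(attr(kept, "dropped"), "a")
  expect_equal(length(filter_bands_by_repeatability(est, 0)), 3)
})

test_that("waveband binning reproduces the 1780-to-178 contract", {
  wl <- as.character(seq(400, 400 + 1779))
  m <- matrix(rnorm(2 * 1780), 2)
  d <- tibble::as_tibble(as.data.frame(m, col.names = wl))
  names(d) <- wl
  d <- dplyr::bind_cols(tibble::tibble(plot_id = c("a", "b")), d)
  out <- bin_wavebands(d, width = 10)
  expect_equal(ncol(out) - 1, 178)
  bm <- attr(out, "bin_map")
  expect_equal(nrow(bm), 178)
  expect_equal(bm$label[1], "R405")  # 400-409 averaged, centre label 405
})

test_that("binning is the arithmetic block mean and drops partial blocks", {
  d <- tibble::tibble(plot_id = "p")
  for (i in 1:25) d[[as.character(699 + i)]] <- i  # 700..724
  out <- bin_wavebands(d, width = 10)
  expect_equal(unname(unlist(out[, -1])), c(5.5, 15.5))  # trailing 5 dropped

  const <- tibble::tibble(plot_id = c("a", "b"))
  for (i in 0:19) const[[as.character(500 + i)]] <- 0.42
  outc <- bin_wavebands(const, width = 10)
  expect_true(all(abs(as.matrix(outc[, -1]) - 0.42) < 1e-12))

  expect_error(bin_wavebands(tibble::tibble(plot_id = "p")),
               class = "phenosel_validation_error")
})

test_that("binning commutes with averaging across plots", {
  set.seed(9)
  d <- tibble::tibble(plot_id = sprintf("p%d", 1:6))
  for (i in 0:19) d[[as.character(600 + i)]] <- rnorm(6)
  binned_then_avg <- colMeans(as.matrix(bin_wavebands(d, width = 10)[, -1]))
  avg <- d |> dplyr::summarise(dplyr::across(-1, mean)) |>
    dplyr::mutate(plot_id = "mean", .before = 1)
  avg_then_binned <- unlist(bin_wavebands(avg, width = 10)[, -1])
  expect_equal(unname(binned_then_avg), unname(avg_then_binned))
})

test_that("vegetation indices follow their standard formulas", {
  d <- tibble::tibble(plot_id = "p", `800` = 0.5, `670` = 0.1)
  out <- compute_vi(d, vi_registry()[vi_registry()$name == "NDVI", ])
  expect_equal(out$NDVI, (0.5 - 0.1) / (0.5 + 0.1), tolerance = 1e-6)

  eq <- tibble::tibble(plot_id = "p", `800` = 0.4, `670` = 0.4)
  expect_equal(compute_vi(eq, vi_registry()[1, ])$NDVI, 0)

  zero <- tibble::tibble(plot_id = "p", `800` = 0.4, `670` = -0.4)
  expect_warning(out0 <- compute_vi(zero, vi_registry()[1, ]), "NDVI")
  expect_true(is.nan(out0$NDVI))

  expect_error(compute_vi(tibble::tibble(plot_id = "p", `800` = 0.5),
                          vi_registry()[1, ]),
               "670", class = "phenosel_validation_error")
})

test_that("indices read from the binned feature containing the wavelength", {
  d <- tibble::tibble(plot_id = "p")
  for (w in seq(660, 809)) d[[as.character(w)]] <- if (w >= 795) 0.5 else 0.1
  binned <- bin_wavebands(d, width = 10)
  out <- compute_vi(binned, vi_registry()[1, ])  # NDVI from R805 vs R665
  expect_equal(out$NDVI, (0.5 - 0.1) / (0.5 + 0.1), tolerance = 1e-6)
})
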