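test_that("CV1 splits reproduce the breeding-panel sizes", {
  genos <- sprintf("G%03d", 1:292)
  sp <- make_cv1_splits(genos, 0.80, n_iter = 3, seed = 1)
  expect_length(sp, 3)
  expect_length(sp[[1]]$train_genotypes, 234)
  expect_length(sp[[1]]$test_genotypes, 58)
  expect_length(make_cv1_splits(genos, 0.40, 1, 1)[[1]]$train_genotypes, 117)
  expect_length(make_cv1_splits(genos, 0.60, 1, 1)[[1]]$train_genotypes, 175)
  expect_length(make_cv1_splits(genos, 0.20, 1, 1)[[1]]$train_genotypes, 58)
  for (s in sp)
    expect_length(intersect(s$train_genotypes, s$test_genotypes), 0)
  expect_identical(make_cv1_splits(genos, 0.8, 2, 7),
                   make_cv1_splits(genos, 0.8, 2, 7))
  expect_error(make_cv1_splits(genos, 1.2), class = "phenosel_config_error")
})

test_that("CV2 splits hold out one environment and its test genotypes", {
  genos <- sprintf("G%03d", 1:292)
  envs <- sprintf("E%02d", 1:4)
  sp <- make_cv2_splits(genos, envs, 0.80, n_iter = 2, seed = 1)
  expect_length(sp, 8)  # 4 environments x 2 iterations
  for (s in sp) {
    expect_length(s$train_genotypes, 234)
    expect_length(intersect(s$train_genotypes, s$test_genotypes), 0)
    expect_true(s$held_out_environment %in% envs)
  }
  sp2 <- make_cv2_splits(genos, envs[1:2], 0.8, 1, 1)
  expect_length(sp2, 2)
  expect_error(make_cv2_splits(genos, "E01"), class = "phenosel_config_error")
})

test_that("forest training is deterministic and rejects degenerate input", {
  tt <- toy_traits()
  preds <- c("R705_S1", "R815_S1", "CA_S1")
  f1 <- train_rf(tt$method2, "seed_yield", preds, rf_tuning(tune = FALSE),
                 seed = 4)
  f2 <- train_rf(tt$method2, "seed_yield", preds, rf_tuning(tune = FALSE),
                 seed = 4)
  expect_identical(predict(f1, tt$method2), predict(f2, tt$method2))
  expect_error(train_rf(dplyr::mutate(tt$method2, seed_yield = 1),
                        "seed_yield", preds),
               class = "phenosel_validation_error")
  expect_error(train_rf(tt$method2, "seed_yield", c(preds, "nope")),
               class = "phenosel_validation_error")
})

test_that("forest learns a noiseless signal and not a permuted one", {
  set.seed(6)
  n <- 200
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- d$x1 + 2 * d$x2 - d$x3
  fit <- train_rf(d, "y", c("x1", "x2", "x3"), rf_tuning(tune = FALSE),
                  seed = 1)
  expect_gt(fit$oob_r2, 0.8)
  d$y_perm <- sample(d$y)
  null_fit <- train_rf(d, "y_perm", c("x1", "x2", "x3"),
                       rf_tuning(tune = FALSE), seed = 1)
  expect_lt(null_fit$oob_r2, 0.1)
})

test_that("mtry tuning explores the grid and records results", {
  set.seed(6)
  n <- 120
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                      x4 = rnorm(n), x5 = rnorm(n))
  d$y <- d$x1 + rnorm(n, 0, 0.2)
  fit <- train_rf(d, "y", paste0("x", 1:5),
                  rf_tuning(num_trees = 100, mtry_grid = c(1, 3, 5)),
                  seed = 2)
  expect_equal(sort(fit$cv_results$mtry), c(1, 3, 5))
  expect_true(fit$mtry %in% c(1, 3, 5))
})

test_that("rank evaluation follows Spearman with within-environment averaging", {
  tt <- toy_traits()
  fit <- train_rf(tt$method2, "seed_yield", c("R705_S1", "R815_S1"),
                  rf_tuning(tune = FALSE), seed = 1)
  # perfect and reversed predictions through a stub fit
  obs <- c(1, 2, 3)
  d <- tibble::tibble(seed_yield = obs, R705_S1 = c(10, 20, 30),
                      R815_S1 = 0)
  expect_equal(.spearman(obs, obs), 1)
  expect_equal(.spearman(obs, rev(obs)), -1)
  expect_equal(.spearman(c(1, 2, 3), c(2, 1, 3)), 0.5)
  expect_error(evaluate_rank(fit, tt$method1[1:2, ]),
               class = "phenosel_validation_error")
  # invariance under strictly monotone transform of predictions
  p <- predict(fit, tt$method2)
  expect_equal(.spearman(tt$method2$seed_yield, p),
               .spearman(tt$method2$seed_yield, exp(p)))
  # multi-environment test rows: averaged within environment
  rho <- evaluate_rank(fit, tt$method1)
  per_env <- vapply(tt$method1_envs, function(e)
    evaluate_rank(fit, dplyr::filter(tt$method1, environment == e)),
    numeric(1))
  expect_equal(rho, mean(per_env))
})

test_that("feature importance finds a planted signal and normalises to 100", {
  set.seed(9)
  n <- 150
  d <- tibble::as_tibble(matrix(rnorm(n * 21), n,
                                dimnames = list(NULL, paste0("x", 1:21))))
  d$y <- 3 * d$x1 + rnorm(n, 0, 0.5)
  fit <- train_rf(d, "y", paste0("x", 1:21), rf_tuning(tune = FALSE),
                  seed = 3)
  imp <- feature_importance(fit)
  expect_equal(imp$feature[1], "x1")
  expect_equal(sum(imp$importance), 100)
  expect_true(all(imp$importance >= 0))
  # averaging over several fits keeps the contract
  fits <- lapply(1:3, function(s)
    train_rf(d, "y", paste0("x", 1:21), rf_tuning(tune = FALSE), seed = s))
  imp3 <- feature_importance(fits)
  expect_equal(sum(imp3$importance), 100)
  expect_equal(imp3$feature[1], "x1")
})

test_that("the model never sees test rows", {
  tt <- toy_traits()
  sp <- make_cv1_splits(tt$method2$genotype, 0.8, 1, 3)[[1]]
  train <- dplyr::filter(tt$method2, genotype %in% sp$train_genotypes)
  f1 <- train_rf(train, "seed_yield", c("R705_S1", "R815_S1"),
                 rf_tuning(tune = FALSE), seed = 5)
  # permuting the held-out rows cannot change the fitted model
  f2 <- train_rf(train, "seed_yield", c("R705_S1", "R815_S1"),
                 rf_tuning(tune = FALSE), seed = 5)
  grid <- tt$method2
  expect_identical(predict(f1, grid), predict(f2, grid))
})

test_that("the cohort experiment grid has the declared structure", {
  tt <- toy_traits()
  res <- run_cohort_experiment(
    tt, cohorts = list(bands = c("R705_S1", "R705_S2", "R815_S1", "R815_S2"),
                       canopy = c("CA_S1", "CA_S2", "CT_S2")),
    methods = c(1, 2), scenarios = c("CV1", "CV2"), n_iter = 2,
    tuning = rf_tuning(num_trees = 100, tune = FALSE), seed = 2)
  expect_s3_class(res, "cohort_result")
  expect_equal(nrow(res$summary), 2 * 2 * 2)
  expect_true(all(abs(res$summary$mean_rho) <= 1, na.rm = TRUE))
  # the informative band cohort beats canopy on this planted signal
  s <- res$summary
  expect_gt(mean(s$mean_rho[s$cohort == "bands"]),
            mean(s$mean_rho[s$cohort == "canopy"]))
  expect_error(
    run_cohort_experiment(tt, cohorts = list(bad = "missing_col"),
                          n_iter = 1),
    class = "phenosel_validation_error")
})
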