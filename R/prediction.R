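#' Cross-validation splits over genotypes (CV1)
#'
#' CV1 emulates predicting untested genotypes in observed environments:
#' in each iteration a random `train_frac` of accessions trains the model
#' and the remainder is tested, in every environment. With 292 accessions at
#' 80/20 this gives 234 training and 58 testing genotypes.
#'
#' @param genotypes Character vector of genotype identifiers.
#' @param train_frac Training fraction in (0, 1).
#' @param n_iter Number of independent random partitions.
#' @param seed Integer seed.
#' @return List of splits; each has `scenario`, `iteration`,
#'   `train_genotypes`, `test_genotypes`.
#' @export
make_cv1_splits <- function(genotypes, train_frac = 0.80, n_iter = 10,
                            seed = 1) {
  if (train_frac <= 0 || train_frac >= 1)
    abort("train_frac must lie in (0, 1)", class = "phenosel_config_error")
  n <- length(genotypes)
  n_train <- round(train_frac * n)
  if (n_train < 1 || n_train >= n)
    abort("split leaves an empty training or testing set",
          class = "phenosel_config_error")
  set.seed(seed)
  lapply(seq_len(n_iter), function(it) {
    tr <- sort(sample(genotypes, n_train))
    list(scenario = "CV1", iteration = it,
         train_genotypes = tr,
         test_genotypes = sort(setdiff(genotypes, tr)),
         held_out_environment = NA_character_)
  })
}

#' Leave-one-environment-out splits over genotypes (CV2)
#'
#' CV2 emulates predicting untested genotypes in an untested environment:
#' for each complete environment `e` and iteration, the model trains on
#' `train_frac` of accessions using rows from every environment except `e`,
#' and is tested on the remaining accessions using rows from `e` only. Test
#' genotypes never appear in training.
#'
#' @param genotypes Character vector of genotype identifiers.
#' @param environments Complete environments to cycle over (>= 2).
#' @inheritParams make_cv1_splits
#' @return List of splits with `held_out_environment` set; one split per
#'   environment per iteration.
#' @export
make_cv2_splits <- function(genotypes, environments, train_frac = 0.80,
                            n_iter = 10, seed = 1) {
  if (length(environments) < 2)
    abort("CV2 needs >= 2 complete environments",
          class = "phenosel_config_error")
  if (train_frac <= 0 || train_frac >= 1)
    abort("train_frac must lie in (0, 1)", class = "phenosel_config_error")
  n_train <- round(train_frac * length(genotypes))
  if (n_train < 1 || n_train >= length(genotypes))
    abort("split leaves an empty training or testing set",
          class = "phenosel_config_error")
  set.seed(seed)
  out <- list()
  for (it in seq_len(n_iter)) {
    for (e in environments) {
      tr <- sort(sample(genotypes, n_train))
      out[[length(out) + 1L]] <- list(
        scenario = "CV2", iteration = it,
        train_genotypes = tr,
        test_genotypes = sort(setdiff(genotypes, tr)),
        held_out_environment = e)
    }
  }
  out
}

#' Random-forest tuning configuration
#'
#' @param num_trees Trees in the final forest (default 500).
#' @param mtry_grid Candidate values for the number of variables tried per
#'   split; `NULL` expands to 5 values spread over the predictor count.
#' @param n_folds,n_repeats Internal cross-validation used for tuning.
#' @param tune Set `FALSE` to skip tuning and use the ranger default mtry.
#' @return A list of class `rf_tuning`.
#' @export
rf_tuning <- function(num_trees = 500, mtry_grid = NULL, n_folds = 5,
                      n_repeats = 1, tune = TRUE) {
  structure(list(num_trees = num_trees, mtry_grid = mtry_grid,
                 n_folds = n_folds, n_repeats = n_repeats, tune = tune),
            class = "rf_tuning")
}

#' Train a random-forest yield predictor
#'
#' Fits a ranger regression forest on the given predictor columns,
#' optionally tuning mtry over a small grid by repeated k-fold
#' cross-validation within the training data. Out-of-bag R-squared and RMSE
#' of the final forest are recorded. Fully deterministic under a fixed seed
#' (single-threaded).
#'
#' @param train Training tibble.
#' @param response Response column name.
#' @param predictors Character vector of predictor columns.
#' @param tuning An [rf_tuning()] configuration.
#' @param seed Integer seed.
#' @return An `rf_fit` object.
#' @export
train_rf <- function(train, response, predictors, tuning = rf_tuning(),
                     seed = 1) {
  missing_cols <- setdiff(c(response, predictors), names(train))
  if (length(missing_cols) > 0)
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "phenosel_validation_error")
  d <- train[, c(response, predictors)]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10)
    abort("too few complete training rows", class = "phenosel_validation_error")
  y <- d[[response]]
  if (sd(y) < 1e-12)
    abort("constant response; nothing to learn",
          class = "phenosel_validation_error")
  X <- as.data.frame(d[, predictors, drop = FALSE])

  grid <- tuning$mtry_grid
  if (is.null(grid) && tuning$tune)
    grid <- unique(pmax(1, round(seq(1, length(predictors), length.out = 5))))
  cv_results <- NULL
  mtry <- NULL
  if (tuning$tune && length(grid) > 1) {
    set.seed(seed)
    res <- list()
    for (rep_i in seq_len(tuning$n_repeats)) {
      fold <- sample(rep_len(seq_len(tuning$n_folds), nrow(d)))
      for (m in grid) {
        errs <- vapply(seq_len(tuning$n_folds), function(k) {
          fit_k <- ranger::ranger(x = X[fold != k, , drop = FALSE],
                                  y = y[fold != k],
                                  num.trees = tuning$num_trees, mtry = m,
                                  seed = seed, num.threads = 1)
          pr <- predict(fit_k, data = X[fold == k, , drop = FALSE],
                        num.threads = 1)$predictions
          sqrt(mean((pr - y[fold == k])^2))
        }, numeric(1))
        res[[length(res) + 1L]] <- tibble(repeat_i = rep_i, mtry = m,
                                          rmse = mean(errs))
      }
    }
    cv_results <- list_rbind(res) |>
      group_by(.data$mtry) |>
      summarise(rmse = mean(.data$rmse), .groups = "drop")
    mtry <- cv_results$mtry[which.min(cv_results$rmse)]
  }
  if (is.null(mtry) && length(grid) == 1) mtry <- min(grid, length(predictors))
  # classical regression default (one third of the predictors)
  if (is.null(mtry)) mtry <- max(1, floor(length(predictors) / 3))

  model <- ranger::ranger(x = X, y = y, num.trees = tuning$num_trees,
                          mtry = mtry, importance = "impurity",
                          seed = seed, num.threads = 1)
  structure(list(model = model, predictors = predictors, response = response,
                 mtry = if (is.null(mtry)) model$mtry else mtry,
                 oob_r2 = model$r.squared,
                 oob_rmse = sqrt(model$prediction.error),
                 cv_results = cv_results, n_train = nrow(d), seed = seed),
            class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("<rf_fit> %d trees, mtry = %d, %d predictors, OOB R2 = %.3f, OOB RMSE = %.4g\n",
              x$model$num.trees, x$mtry, length(x$predictors), x$oob_r2,
              x$oob_rmse))
  invisible(x)
}

#' @export
predict.rf_fit <- function(object, newdata, ...) {
  predict(object$model,
          data = as.data.frame(newdata[, object$predictors, drop = FALSE]),
          num.threads = 1)$predictions
}

#' @exportS3Method
glance.rf_fit <- function(x, ...) {
  tibble(n_train = x$n_train, mtry = x$mtry, num_trees = x$model$num.trees,
         oob_r2 = x$oob_r2, oob_rmse = x$oob_rmse)
}

.spearman <- function(a, b) suppressWarnings(cor(a, b, method = "spearman"))

#' Rank-prediction accuracy on a held-out test set
#'
#' Spearman rank correlation between observed and predicted values. When the
#' test rows span several environments the correlation is computed within
#' each environment and averaged (a pooled correlation is available via
#' `by_environment = FALSE`).
#'
#' @param fit An `rf_fit`.
#' @param test Test tibble, disjoint from training genotypes.
#' @param response Observed response column.
#' @param by_environment Average within-environment correlations (default).
#' @return Single Spearman rho.
#' @export
evaluate_rank <- function(fit, test, response = fit$response,
                          by_environment = TRUE) {
  d <- test[complete.cases(test[, c(response, fit$predictors)]), ,
            drop = FALSE]
  if (nrow(d) < 3)
    abort("need >= 3 complete test rows", class = "phenosel_validation_error")
  pred <- predict(fit, d)
  obs <- d[[response]]
  if (by_environment && "environment" %in% names(d) &&
      length(unique(d$environment)) > 1) {
    rho <- d |>
      mutate(.pred = pred, .obs = obs) |>
      group_by(.data$environment) |>
      summarise(rho = .spearman(.data$.obs, .data$.pred), .groups = "drop")
    mean(rho$rho, na.rm = TRUE)
  } else {
    .spearman(obs, pred)
  }
}

#' Averaged, normalised feature importance
#'
#' Impurity importances of one or several forests (e.g. across CV
#' iterations), averaged per feature and normalised to sum to 100.
#'
#' @param fits An `rf_fit` or a list of them.
#' @return Tibble `feature`, `importance`, sorted decreasing; sums to 100.
#' @export
feature_importance <- function(fits) {
  if (inherits(fits, "rf_fit")) fits <- list(fits)
  imps <- lapply(fits, function(f) ranger::importance(f$model))
  feats <- names(imps[[1]])
  m <- sapply(imps, function(v) v[feats])
  avg <- if (is.matrix(m)) rowMeans(m) else m
  avg <- pmax(avg, 0)
  total <- sum(avg)
  if (total <= 0) avg[] <- 100 / length(avg) else avg <- 100 * avg / total
  tibble(feature = feats, importance = unname(avg)) |>
    arrange(desc(.data$importance))
}

# assemble train/test tables for a (method, split) combination
.split_tables <- function(traits, method, split) {
  m1 <- traits$method1
  m2 <- traits$method2
  if (method == 1) {
    if (split$scenario == "CV1") {
      train <- m1 |> filter(.data$genotype %in% split$train_genotypes)
      test <- m1 |> filter(.data$genotype %in% split$test_genotypes)
    } else {
      train <- m1 |>
        filter(.data$genotype %in% split$train_genotypes,
               .data$environment != split$held_out_environment)
      test <- m1 |>
        filter(.data$genotype %in% split$test_genotypes,
               .data$environment == split$held_out_environment)
    }
  } else {
    train <- m2 |> filter(.data$genotype %in% split$train_genotypes)
    test <- if (split$scenario == "CV1")
      m1 |> filter(.data$genotype %in% split$test_genotypes)
    else
      m1 |> filter(.data$genotype %in% split$test_genotypes,
                   .data$environment == split$held_out_environment)
  }
  list(train = train, test = test)
}

#' Run the predictor-cohort comparison experiment
#'
#' Trains and evaluates random-forest rank predictors for every combination
#' of preprocessing method (1: by-environment BLUPs; 2: across-environment
#' BLUPs), cross-validation scenario (CV1, CV2) and predictor cohort, over
#' `n_iter` random partitions. CV2 correlations are averaged over held-out
#' environments within an iteration.
#'
#' @param traits A `phenosel_traits` object.
#' @param cohorts Named list of predictor column sets; default
#'   [default_cohorts()].
#' @param methods Preprocessing methods to evaluate (subset of `c(1, 2)`).
#' @param scenarios Scenarios to evaluate (subset of `c("CV1", "CV2")`).
#' @param n_iter Partitions per scenario.
#' @param train_frac Training fraction.
#' @param response Response column.
#' @param tuning [rf_tuning()] configuration.
#' @param seed Integer seed.
#' @return A `cohort_result` with per-iteration `results` and a `summary`
#'   tibble of mean and SD rho per cell.
#' @export
run_cohort_experiment <- function(traits,
                                  cohorts = default_cohorts(traits),
                                  methods = c(1, 2),
                                  scenarios = c("CV1", "CV2"),
                                  n_iter = 10,
                                  train_frac = 0.80,
                                  response = "seed_yield",
                                  tuning = rf_tuning(tune = FALSE),
                                  seed = 1) {
  for (co in names(cohorts)) {
    missing_cols <- setdiff(cohorts[[co]], names(traits$method1))
    if (length(missing_cols) > 0)
      abort(paste0("cohort '", co, "' references missing column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "phenosel_validation_error")
  }
  genos <- traits$method2$genotype
  # paired design: CV1 and CV2 share the genotype partition of an iteration,
  # so the scenario contrast is not confounded with partition luck
  base_splits <- make_cv1_splits(genos, train_frac, n_iter, seed)
  splits <- list()
  for (sp in base_splits) {
    if ("CV1" %in% scenarios) splits <- c(splits, list(sp))
    if ("CV2" %in% scenarios)
      for (e in traits$method1_envs) {
        sp2 <- sp
        sp2$scenario <- "CV2"
        sp2$held_out_environment <- e
        splits <- c(splits, list(sp2))
      }
  }
  rows <- list()
  for (method in methods) {
    for (sp in splits) {
      tabs <- .split_tables(traits, method, sp)
      for (co in names(cohorts)) {
        fit_seed <- seed + 101 * sp$iteration + method
        rho <- tryCatch({
          fit <- train_rf(tabs$train, response, cohorts[[co]], tuning,
                          seed = fit_seed)
          evaluate_rank(fit, tabs$test, response)
        }, error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- tibble(
          method = method, scenario = sp$scenario, cohort = co,
          iteration = sp$iteration,
          held_out_environment = sp$held_out_environment, rho = rho)
      }
    }
  }
  results <- list_rbind(rows) |>
    group_by(.data$method, .data$scenario, .data$cohort, .data$iteration) |>
    summarise(rho = mean(.data$rho, na.rm = TRUE), .groups = "drop")
  summary <- results |>
    group_by(.data$method, .data$scenario, .data$cohort) |>
    summarise(mean_rho = mean(.data$rho, na.rm = TRUE),
              sd_rho = sd(.data$rho), n_iter = dplyr::n(), .groups = "drop")
  structure(list(results = results, summary = summary),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result>\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @exportS3Method
tidy.cohort_result <- function(x, ...) x$summary
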