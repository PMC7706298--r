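#' Confusion-matrix metrics at a selection intensity
#'
#' "Positive" is membership in the top `round(intensity * n)` (at least 1)
#' of the ranking, determined separately for observed and predicted values;
#' ties are broken by the stable order of the genotype identifiers. From the
#' resulting counts:
#' \deqn{SPE = TN/(TN+FP)}
#' \deqn{FS = 2TP/(2TP+FP+FN)}
#' \deqn{BAC = \left(\frac{TP}{TP+FN} + \frac{TN}{TN+FP}\right)/2}
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 5).
#' @param intensity Selected fraction (default 0.20).
#' @param ids Optional identifiers used for deterministic tie-breaking.
#' @return One-row tibble: `TP`, `TN`, `FP`, `FN`, `SPE`, `BAC`, `FS`,
#'   `intensity`, `n`, `k`.
#' @export
#' @examples
#' confusion_at_intensity(10:1, 10:1, 0.2)  # perfect ranking
confusion_at_intensity <- function(observed, predicted, intensity = 0.20,
                                   ids = NULL) {
  n <- length(observed)
  if (length(predicted) != n)
    abort("observed and predicted must have equal length",
          class = "phenosel_validation_error")
  if (n < 5)
    abort("need n >= 5 for selection metrics",
          class = "phenosel_validation_error")
  if (intensity <= 0 || intensity > 1)
    abort("intensity must select at least one candidate (0 < intensity <= 1)",
          class = "phenosel_validation_error")
  if (is.null(ids)) ids <- seq_len(n)
  k <- max(1L, round(intensity * n))
  top_obs <- order(-observed, ids)[seq_len(k)]
  top_pred <- order(-predicted, ids)[seq_len(k)]
  tp <- length(intersect(top_obs, top_pred))
  fp <- k - tp
  fn <- k - tp
  tn <- n - k - fp
  spe <- tn / (tn + fp)
  bac <- (tp / (tp + fn) + tn / (tn + fp)) / 2
  fs <- 2 * tp / (2 * tp + fp + fn)
  tibble(TP = tp, TN = tn, FP = fp, FN = fn,
         SPE = spe, BAC = bac, FS = fs,
         intensity = intensity, n = n, k = k)
}

# mean confusion metrics over environments of a multi-environment test set
.confusion_by_env <- function(test, obs_col, pred, intensity) {
  d <- test |> mutate(.pred = pred)
  envs <- if ("environment" %in% names(d)) unique(d$environment) else "all"
  rows <- list()
  for (e in envs) {
    de <- if ("environment" %in% names(d))
      d |> filter(.data$environment == e) else d
    if (nrow(de) < 5) next
    rows[[length(rows) + 1L]] <-
      confusion_at_intensity(de[[obs_col]], de$.pred, intensity,
                             ids = de$genotype)
  }
  if (length(rows) == 0) return(NULL)
  list_rbind(rows) |>
    summarise(SPE = mean(.data$SPE), BAC = mean(.data$BAC),
              FS = mean(.data$FS))
}

#' Training-population-size study
#'
#' Re-runs the optimized prediction models while shrinking the training
#' fraction (80, 60, 40, 20% by default), under both cross-validation
#' scenarios, comparing the multisensor model (selected wavebands + best VI
#' + canopy traits) with a wavebands-only model. For every cell the mean
#' Spearman rank correlation and the selection metrics at the given
#' intensity are reported over `n_iter` random partitions.
#'
#' @param traits A `phenosel_traits` object.
#' @param selected_bins Bin labels from the GA step.
#' @param fractions Training fractions to test.
#' @param scenarios Subset of `c("CV1", "CV2")`.
#' @param models Subset of `c("multisensor", "wavebands")`.
#' @param rg_table,vi Passed to [assemble_final_model()] to pick the VI.
#' @param n_iter Partitions per fraction.
#' @param intensity Selection intensity for the confusion metrics.
#' @param response Response column.
#' @param tuning [rf_tuning()] configuration.
#' @param seed Integer seed.
#' @return A `size_study` with `results` (per iteration) and `summary`.
#' @export
training_size_study <- function(traits, selected_bins,
                                fractions = c(0.80, 0.60, 0.40, 0.20),
                                scenarios = c("CV1", "CV2"),
                                models = c("multisensor", "wavebands"),
                                rg_table = NULL, vi = NULL,
                                n_iter = 10, intensity = 0.20,
                                response = "seed_yield",
                                tuning = rf_tuning(tune = FALSE),
                                seed = 1) {
  m1 <- traits$method1
  genos <- traits$method2$genotype
  band_feats <- grep(paste0("^(", paste(selected_bins, collapse = "|"),
                            ")_S\\d$"), names(m1), value = TRUE)
  if (is.null(vi) && !is.null(rg_table)) {
    vi_rows <- rg_table |>
      filter(grepl(paste0("^(", paste(traits$vi_names, collapse = "|"),
                          ")_S\\d$"), .data$trait), !is.na(.data$rg))
    if (nrow(vi_rows) > 0)
      vi <- sub("_S\\d$", "", vi_rows$trait[which.max(abs(vi_rows$rg))])
  }
  if (is.null(vi)) vi <- "VREI2"
  vi_feats <- grep(paste0("^", vi, "_S\\d$"), names(m1), value = TRUE)
  canopy_feats <- grep("^(CA|CT)_S\\d$", names(m1), value = TRUE)
  feature_sets <- list(
    multisensor = c(band_feats, vi_feats, canopy_feats),
    wavebands = band_feats
  )[models]

  rows <- list()
  for (fi in seq_along(fractions)) {
    frac <- fractions[fi]
    if (round(frac * length(genos)) < 10)
      abort(paste0("fraction ", frac, " leaves < 10 training genotypes"),
            class = "phenosel_config_error")
    splits <- list()
    if ("CV1" %in% scenarios)
      splits <- c(splits, make_cv1_splits(genos, frac, n_iter,
                                          seed + 10 * fi))
    if ("CV2" %in% scenarios)
      splits <- c(splits, make_cv2_splits(genos, traits$method1_envs, frac,
                                          n_iter, seed + 10 * fi + 1))
    for (sp in splits) {
      tabs <- .split_tables(traits, 1, sp)
      for (mod in names(feature_sets)) {
        feats <- feature_sets[[mod]]
        cell <- tryCatch({
          fit <- train_rf(tabs$train, response, feats, tuning,
                          seed = seed + sp$iteration)
          test <- tabs$test[complete.cases(tabs$test[, c(response, feats)]), ]
          rho <- evaluate_rank(fit, test, response)
          conf <- .confusion_by_env(test, response, predict(fit, test),
                                    intensity)
          bind_cols(tibble(rho = rho), conf)
        }, error = function(e) tibble(rho = NA_real_, SPE = NA_real_,
                                      BAC = NA_real_, FS = NA_real_))
        rows[[length(rows) + 1L]] <- bind_cols(
          tibble(fraction = frac, scenario = sp$scenario, model = mod,
                 iteration = sp$iteration), cell)
      }
    }
  }
  results <- list_rbind(rows) |>
    group_by(.data$fraction, .data$scenario, .data$model, .data$iteration) |>
    summarise(across(c("rho", "SPE", "BAC", "FS"), ~ mean(.x, na.rm = TRUE)),
              .groups = "drop")
  summary <- results |>
    group_by(.data$fraction, .data$scenario, .data$model) |>
    summarise(across(c("rho", "SPE", "BAC", "FS"),
                     list(mean = ~ mean(.x, na.rm = TRUE),
                          sd = ~ sd(.x, na.rm = TRUE))),
              .groups = "drop")
  structure(list(results = results, summary = summary,
                 intensity = intensity, vi = vi),
            class = "size_study")
}

#' @export
print.size_study <- function(x, ...) {
  cat("<size_study> selection intensity", x$intensity, "\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @exportS3Method
tidy.size_study <- function(x, ...) x$summary
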