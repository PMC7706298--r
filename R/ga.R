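#' Genetic-algorithm configuration for waveband selection
#'
#' Standard wrapper-selection settings sized to desk scale; every value is
#' adjustable. By default a chromosome is a set of `n_select` spectral bins,
#' each contributing its feature at both growth stages ("stage-shared"
#' semantics, matching a camera whose filters observe every flight); setting
#' `stage_shared = FALSE` instead searches the stage-tagged feature space
#' directly.
#'
#' @param n_select Number of bins per chromosome (default 4, the band count
#'   of customizable multispectral cameras).
#' @param population_size,n_generations,crossover_rate,mutation_rate,elitism,tournament_size
#'   Usual GA controls; uniform crossover, per-gene mutation to an unused
#'   bin, tournament selection with elitism.
#' @param fitness_folds Internal genotype-k-fold used to score a chromosome.
#' @param fitness_num_trees Trees of the fitness forest (reduced during the
#'   search; the final model uses a full forest).
#' @param patience Generations without best-fitness improvement before an
#'   early stop.
#' @param stage_shared Chromosome semantics (see above).
#' @param seed Integer seed.
#' @return `ga_config` list.
#' @export
ga_config <- function(n_select = 4, population_size = 50, n_generations = 30,
                      crossover_rate = 0.8, mutation_rate = 0.1, elitism = 2,
                      tournament_size = 3, fitness_folds = 5,
                      fitness_num_trees = 100, patience = 10,
                      stage_shared = TRUE, seed = 1) {
  if (n_select < 1)
    abort("n_select must be >= 1", class = "phenosel_config_error")
  if (population_size <= elitism)
    abort("population_size must exceed elitism",
          class = "phenosel_config_error")
  rates <- c(crossover_rate, mutation_rate)
  if (any(rates < 0 | rates > 1))
    abort("rates must lie in [0, 1]", class = "phenosel_config_error")
  structure(list(n_select = as.integer(n_select),
                 population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism),
                 tournament_size = as.integer(tournament_size),
                 fitness_folds = as.integer(fitness_folds),
                 fitness_num_trees = as.integer(fitness_num_trees),
                 patience = as.integer(patience),
                 stage_shared = isTRUE(stage_shared),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Candidate feature space for waveband optimization
#'
#' Enumerates the stage-tagged binned waveband features of a trait table.
#' Both growth stages must carry the identical bin grid; with 178 bins per
#' stage the space has 356 candidate features.
#'
#' @param data Trait table with `R<nm>_S1` / `R<nm>_S2` columns (e.g.
#'   `traits$method1`), or a `phenosel_traits` object.
#' @return Tibble `feature`, `bin`, `stage`, `center` (nm).
#' @export
build_search_space <- function(data) {
  if (inherits(data, "phenosel_traits")) data <- data$method1
  cols <- grep("^R\\d+_S\\d$", names(data), value = TRUE)
  if (length(cols) == 0)
    abort("no binned waveband columns found", class = "phenosel_validation_error")
  bin <- sub("_S\\d$", "", cols)
  stage <- sub("^.*_(S\\d)$", "\\1", cols)
  stages <- sort(unique(stage))
  grids <- lapply(stages, function(s) sort(unique(bin[stage == s])))
  if (length(stages) > 1 &&
      !all(vapply(grids[-1], identical, logical(1), grids[[1]])))
    abort("growth stages carry different bin grids",
          class = "phenosel_validation_error")
  tibble(feature = cols, bin = bin, stage = stage,
         center = as.numeric(sub("^R", "", bin)))
}

# expand a chromosome (bin indices or feature indices) to feature columns
.chromosome_features <- function(chromosome, space, stage_shared) {
  if (stage_shared) {
    bins <- sort(unique(space$bin))
    b <- bins[chromosome]
    space$feature[space$bin %in% b]
  } else {
    space$feature[chromosome]
  }
}

#' Score a chromosome by cross-validated rank correlation
#'
#' Trains a reduced random forest on the chromosome's expanded features and
#' returns the mean Spearman rank correlation over an internal k-fold split
#' of the training genotypes (the held-out test set is never touched).
#' Chromosomes with any zero-variance feature score -1. Scores are cached by
#' chromosome key when a cache environment is supplied.
#'
#' @param chromosome Integer vector of distinct bin (or feature) indices.
#' @param data Training trait table (rows of training genotypes only).
#' @param space Search space from [build_search_space()].
#' @param config A [ga_config()].
#' @param response Response column.
#' @param folds Optional prebuilt genotype-fold assignment (named integer
#'   vector); built from `config$seed` otherwise.
#' @param cache Optional environment used as a fitness cache.
#' @param rf_seed Seed of the fitness forests (default `config$seed`); fix
#'   it across runs sharing `folds` so the cached objective is identical.
#' @return Fitness in `[-1, 1]`.
#' @export
evaluate_fitness <- function(chromosome, data, space, config,
                             response = "seed_yield", folds = NULL,
                             cache = NULL, rf_seed = config$seed) {
  key <- paste(sort(chromosome), collapse = "-")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  feats <- .chromosome_features(chromosome, space, config$stage_shared)
  d <- data[complete.cases(data[, c(response, feats)]), , drop = FALSE]
  fitness <- if (any(vapply(d[feats], function(v) sd(v) < 1e-12, logical(1))))
    -1
  else {
    genos <- sort(unique(d$genotype))
    if (is.null(folds)) {
      set.seed(config$seed)
      folds <- setNames(sample(rep_len(seq_len(config$fitness_folds),
                                       length(genos))), genos)
    }
    rhos <- vapply(seq_len(config$fitness_folds), function(k) {
      tr <- d[folds[d$genotype] != k, , drop = FALSE]
      te <- d[folds[d$genotype] == k, , drop = FALSE]
      if (nrow(te) < 3 || nrow(tr) < 10) return(NA_real_)
      fit <- train_rf(tr, response, feats,
                      rf_tuning(num_trees = config$fitness_num_trees,
                                tune = FALSE),
                      seed = rf_seed)
      evaluate_rank(fit, te, response)
    }, numeric(1))
    mean(rhos, na.rm = TRUE)
  }
  if (!is.null(cache)) cache[[key]] <- fitness
  fitness
}

#' Select optimal wavebands by genetic-algorithm search
#'
#' Wrapper feature selection: chromosomes are sets of `n_select` distinct
#' spectral bins (shared across growth stages by default, so 4 bins expand
#' to 8 model features); fitness is the cross-validated rank correlation of
#' a random-forest yield predictor restricted to those features. Tournament
#' selection, uniform crossover repaired to distinctness, per-gene mutation
#' to an unused bin, elitism, and early stopping on a stalled best fitness.
#' With `n_generations = 0` the result is the best chromosome of the random
#' initial population.
#'
#' @param data Training trait table (Method-1 rows of training genotypes).
#' @param config A [ga_config()].
#' @param response Response column.
#' @param fitness_folds Optional prebuilt genotype-fold assignment (named
#'   integer vector). Passing the same folds to several runs makes them
#'   replicate searches of one fixed objective, so their fitness caches can
#'   be shared.
#' @param fitness_cache Optional environment used as the fitness cache;
#'   reusable across runs that share `fitness_folds`.
#' @return A `ga_result`: `best_bins` (labels), `selected_wavelengths` (bin
#'   centres, nm), `fitness`, per-generation `log`, `n_evaluations`.
#' @export
run_ga <- function(data, config = ga_config(), response = "seed_yield",
                   fitness_folds = NULL, fitness_cache = NULL) {
  space <- build_search_space(data)
  n_items <- if (config$stage_shared) length(unique(space$bin))
  else nrow(space)
  if (n_items < config$n_select)
    abort("search space smaller than n_select", class = "phenosel_config_error")
  set.seed(config$seed)
  genos <- sort(unique(data$genotype))
  folds <- if (!is.null(fitness_folds)) fitness_folds
  else setNames(sample(rep_len(seq_len(config$fitness_folds),
                               length(genos))), genos)
  cache <- if (!is.null(fitness_cache)) fitness_cache
  else new.env(parent = emptyenv())
  rf_seed <- if (!is.null(fitness_folds))
    attr(fitness_folds, "rf_seed") %||% 1L else config$seed
  score <- function(ch) evaluate_fitness(ch, data, space, config, response,
                                         folds = folds, cache = cache,
                                         rf_seed = rf_seed)

  pop <- replicate(config$population_size,
                   sort(sample.int(n_items, config$n_select)),
                   simplify = FALSE)
  fitness <- vapply(pop, score, numeric(1))
  log_rows <- list(tibble(generation = 0L, best = max(fitness),
                          mean = mean(fitness)))
  best_idx <- which.max(fitness)
  best <- pop[[best_idx]]; best_fit <- fitness[best_idx]
  stall <- 0L

  tournament <- function() {
    cand <- sample.int(config$population_size, config$tournament_size)
    pop[[cand[which.max(fitness[cand])]]]
  }
  repair <- function(ch) {
    ch <- unique(ch)
    while (length(ch) < config$n_select)
      ch <- c(ch, sample(setdiff(seq_len(n_items), ch), 1))
    sort(ch[seq_len(config$n_select)])
  }

  gen <- 0L
  while (gen < config$n_generations) {
    gen <- gen + 1L
    elite <- pop[order(fitness, decreasing = TRUE)[seq_len(config$elitism)]]
    offspring <- list()
    while (length(offspring) < config$population_size - config$elitism) {
      p1 <- tournament(); p2 <- tournament()
      child <- if (runif(1) < config$crossover_rate) {
        mask <- runif(config$n_select) < 0.5
        repair(c(p1[mask], p2[!mask]))
      } else p1
      mut <- runif(config$n_select) < config$mutation_rate
      if (any(mut)) {
        unused <- setdiff(seq_len(n_items), child)
        for (g in which(mut))
          if (length(unused) > 0) {
            pick <- if (length(unused) == 1) unused else sample(unused, 1)
            unused <- c(setdiff(unused, pick), child[g])
            child[g] <- pick
          }
        child <- sort(child)
      }
      offspring[[length(offspring) + 1L]] <- child
    }
    pop <- c(elite, offspring)
    fitness <- vapply(pop, score, numeric(1))
    gen_best <- max(fitness)
    log_rows[[length(log_rows) + 1L]] <-
      tibble(generation = gen, best = gen_best, mean = mean(fitness))
    if (gen_best > best_fit + 1e-12) {
      best_fit <- gen_best
      best <- pop[[which.max(fitness)]]
      stall <- 0L
    } else stall <- stall + 1L
    if (stall >= config$patience) break
  }

  bins <- sort(unique(space$bin))
  best_bins <- if (config$stage_shared) bins[best]
  else unique(space$bin[best])
  structure(list(
    best_chromosome = best,
    best_bins = best_bins,
    selected_wavelengths = as.numeric(sub("^R", "", best_bins)),
    fitness = best_fit,
    log = list_rbind(log_rows),
    n_evaluations = length(ls(cache)),
    config = config,
    space = space
  ), class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %d generations, %d unique evaluations\n",
              max(x$log$generation), x$n_evaluations))
  cat(sprintf("  selected: %s (fitness %.3f)\n",
              paste(x$best_bins, collapse = ", "), x$fitness))
  invisible(x)
}

#' @exportS3Method
glance.ga_result <- function(x, ...) {
  tibble(fitness = x$fitness, n_generations = max(x$log$generation),
         n_evaluations = x$n_evaluations,
         bins = paste(x$best_bins, collapse = ","))
}

#' Assemble the final multisensor prediction model
#'
#' Retrains a full random forest on the GA-selected bins (expanded to both
#' growth stages) supplemented with the vegetation index of strongest
#' genetic correlation with yield and the canopy traits (area,
#' temperature) - the trait set a multispectral camera plus RGB and thermal
#' sensors can deliver.
#'
#' @param traits A `phenosel_traits` object.
#' @param train_genotypes Genotypes allowed into training.
#' @param selected_bins Bin labels (e.g. from `ga_result$best_bins`).
#' @param rg_table Genetic-correlation table
#'   ([genetic_correlation_table()]); used to pick the VI of maximum
#'   absolute genetic correlation.
#' @param vi Explicit VI base name overriding the `rg_table` choice.
#' @param include_canopy Include canopy trait columns (default TRUE; a
#'   warning is raised and the model proceeds without them if absent).
#' @param response Response column.
#' @param tuning [rf_tuning()] for the final forest (500 trees by default).
#' @param seed Integer seed.
#' @return A `final_model` list: `fit`, `features`, `vi`.
#' @export
assemble_final_model <- function(traits, train_genotypes, selected_bins,
                                 rg_table = NULL, vi = NULL,
                                 include_canopy = TRUE,
                                 response = "seed_yield",
                                 tuning = rf_tuning(tune = FALSE),
                                 seed = 1) {
  m1 <- traits$method1
  band_feats <- grep(paste0("^(", paste(selected_bins, collapse = "|"),
                            ")_S\\d$"), names(m1), value = TRUE)
  if (is.null(vi)) {
    if (!is.null(rg_table)) {
      vi_rows <- rg_table |>
        filter(grepl(paste0("^(", paste(traits$vi_names, collapse = "|"),
                            ")_S\\d$"), .data$trait),
               !is.na(.data$rg))
      if (nrow(vi_rows) > 0)
        vi <- sub("_S\\d$", "", vi_rows$trait[which.max(abs(vi_rows$rg))])
    }
    if (is.null(vi)) vi <- "VREI2"
  }
  vi_feats <- grep(paste0("^", vi, "_S\\d$"), names(m1), value = TRUE)
  canopy_feats <- character(0)
  if (include_canopy) {
    canopy_feats <- grep("^(CA|CT)_S\\d$", names(m1), value = TRUE)
    if (length(canopy_feats) == 0)
      warn("no canopy trait columns found; final model runs without them")
  }
  features <- c(band_feats, vi_feats, canopy_feats)
  train <- m1 |> filter(.data$genotype %in% train_genotypes)
  fit <- train_rf(train, response, features, tuning, seed = seed)
  structure(list(fit = fit, features = features, vi = vi,
                 selected_bins = selected_bins),
            class = "final_model")
}

#' @export
print.final_model <- function(x, ...) {
  cat("<final_model> bands:", paste(x$selected_bins, collapse = ", "),
      "| VI:", x$vi, "\n")
  print(x$fit)
  invisible(x)
}
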