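#' Fit the multi-environment trial mixed model by REML
#'
#' Fits the all-random alpha-lattice model
#' \deqn{y = \mu + E + R + B(R) + G + G{\times}E + \varepsilon}
#' with lme4, where replicates are nested in environments and incomplete
#' blocks in replicates (identifiers are expanded to unique levels
#' internally). Random terms with fewer than two observed levels are dropped
#' with a message, so the same call covers reduced models (e.g. a
#' single-environment fit loses all environment terms).
#'
#' @param data Tibble with design columns `environment`, `replicate`,
#'   `block`, `genotype` (those present are used) and the response.
#' @param response Name of the response column.
#' @param random Random terms to include, a subset of
#'   `c("environment", "replicate", "block", "genotype",
#'   "genotype:environment")`.
#' @param reuse Optional `mm_fit` of another response on the *identical*
#'   design rows (same observations, same order, same missingness); the
#'   fitted model structure is reused via [lme4::refit()], which is several
#'   times faster than a fresh fit. Used when fitting many traits measured
#'   on the same plots (e.g. hundreds of wavebands).
#' @return An `mm_fit` object: variance components, grand mean, BLUPs per
#'   random term, fitted values and residuals.
#' @export
fit_mixed_model <- function(data,
                            response,
                            random = c("environment", "replicate", "block",
                                       "genotype", "genotype:environment"),
                            reuse = NULL) {
  if (!response %in% names(data))
    abort(paste0("response column not found: ", response),
          class = "phenosel_validation_error")
  random <- match.arg(random, several.ok = TRUE)
  df <- as.data.frame(data)
  df$.y <- df[[response]]
  df <- df[!is.na(df$.y), , drop = FALSE]
  if (nrow(df) < 3)
    abort("too few non-missing observations", class = "phenosel_validation_error")

  has_env <- "environment" %in% names(df) &&
    length(unique(df$environment)) > 1
  # unique level expansion for nested terms
  if ("replicate" %in% names(df))
    df$.rep <- if ("environment" %in% names(df))
      paste(df$environment, df$replicate, sep = ":") else df$replicate
  if ("block" %in% names(df))
    df$.block <- if ("replicate" %in% names(df))
      paste(df$.rep, df$block, sep = ":") else df$block

  term_var <- c(environment = "environment", replicate = ".rep",
                block = ".block", genotype = "genotype",
                "genotype:environment" = ".gxe")
  if ("genotype:environment" %in% random)
    df$.gxe <- paste(df$genotype, df$environment, sep = ":")

  kept <- character(0)
  for (tm in random) {
    v <- term_var[[tm]]
    if (!v %in% names(df)) next
    if (tm %in% c("environment", "genotype:environment") && !has_env) next
    nl <- length(unique(df[[v]]))
    if (tm == "genotype:environment" && nl >= nrow(df)) next  # confounded with residual
    if (nl >= 2) kept <- c(kept, tm)
  }
  dropped <- setdiff(random, kept)
  if (length(dropped) > 0)
    inform(paste0("dropping inestimable random term(s): ",
                  paste(dropped, collapse = ", ")))
  if (length(kept) == 0)
    abort("no estimable random terms", class = "phenosel_validation_error")

  fml <- as.formula(paste(".y ~ 1 +",
                          paste(sprintf("(1 | %s)", term_var[kept]),
                                collapse = " + ")))
  fit <- if (!is.null(reuse) &&
               identical(reuse$random_terms, kept) &&
               reuse$n_obs == nrow(df)) {
    lme4::refit(reuse$model, newresp = df$.y)
  } else {
    lme4::lmer(fml, data = df, REML = TRUE,
               control = lme4::lmerControl(
                 calc.derivs = FALSE,
                 check.conv.singular = "ignore",
                 check.nobs.vs.nlev = "ignore",
                 check.nobs.vs.nRE = "ignore"))
  }
  vc_df <- as.data.frame(lme4::VarCorr(fit))
  var_of <- function(v) {
    hit <- vc_df$grp == v
    if (any(hit)) vc_df$vcov[hit][1] else NA_real_
  }
  vc <- tibble(
    term = c(kept, "residual"),
    variance = c(vapply(term_var[kept], var_of, numeric(1)),
                 vc_df$vcov[vc_df$grp == "Residual"][1])
  )
  re <- lme4::ranef(fit)
  blups <- imap(re, function(b, v) {
    tm <- names(term_var)[match(v, term_var)]
    tibble(term = tm, level = rownames(b), blup = b[["(Intercept)"]])
  })
  names(blups) <- vapply(blups, function(b) b$term[1], character(1))
  msgs <- fit@optinfo$conv$lme4$messages
  structure(list(
    model = fit,
    mu = unname(lme4::fixef(fit)[1]),
    vc = vc,
    blups = blups,
    fitted = fitted(fit),
    residuals = resid(fit),
    sigma = stats::sigma(fit),
    converged = is.null(msgs),
    n_obs = nrow(df),
    response = response,
    random_terms = kept,
    data = as_tibble(df[setdiff(names(df), c(".y", ".rep", ".block", ".gxe"))])
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit> REML fit of '", x$response, "' (", x$n_obs, " obs)\n", sep = "")
  print(as.data.frame(x$vc), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method
tidy.mm_fit <- function(x, ...) x$vc

#' @exportS3Method
glance.mm_fit <- function(x, ...) {
  tibble(n_obs = x$n_obs, sigma = x$sigma,
         logLik = as.numeric(logLik(x$model)),
         converged = x$converged)
}

#' Genotype BLUPs of a fitted trial model
#'
#' @param fit An `mm_fit` object with a genotype term.
#' @return Tibble with `genotype`, `blup` (shrunken deviation) and
#'   `predicted` (grand mean + BLUP).
#' @export
genotype_blups <- function(fit) {
  stopifnot(inherits(fit, "mm_fit"))
  b <- fit$blups[["genotype"]]
  if (is.null(b))
    abort("fit has no genotype term", class = "phenosel_validation_error")
  tibble(genotype = b$level, blup = b$blup, predicted = fit$mu + b$blup)
}

#' Flag and refit after studentized-residual outlier removal
#'
#' Conditional residuals are studentized as
#' \eqn{r_i / (\hat\sigma\sqrt{1 - h_{ii}})} using the hat values of the
#' mixed-model fit; observations beyond the threshold in absolute value are
#' removed and the model refit once (no iterative re-flagging).
#'
#' @param fit An `mm_fit` object.
#' @param threshold Absolute studentized-residual cutoff (default 3).
#' @return List with `fit` (refit on clean data, or the original fit when
#'   nothing was flagged), `clean` (tibble), `flagged` (tibble with the
#'   studentized residuals of removed rows).
#' @export
remove_outliers_studentized <- function(fit, threshold = 3) {
  stopifnot(inherits(fit, "mm_fit"))
  h <- pmin(hatvalues(fit$model), 0.999)
  stud <- fit$residuals / (fit$sigma * sqrt(1 - h))
  out <- abs(stud) > threshold
  flagged <- fit$data[out, , drop = FALSE]
  if (nrow(flagged) > 0) flagged$studentized <- stud[out]
  if (mean(out) > 0.20)
    warn(paste0(round(100 * mean(out)), "% of observations flagged; ",
                "possible model misfit"))
  if (!any(out))
    return(list(fit = fit, clean = fit$data, flagged = flagged))
  clean <- fit$data[!out, , drop = FALSE]
  refit <- fit_mixed_model(clean, fit$response, random = fit$random_terms)
  list(fit = refit, clean = clean, flagged = as_tibble(flagged))
}

#' By-environment genotype BLUPs (Method 1)
#'
#' Fits, separately within each environment, the reduced all-random model
#' \eqn{y = \mu + R + B(R) + G + \varepsilon} (all environment terms
#' removed) and returns the genotype BLUPs per environment. Suited to trials
#' where some environments have sparse phenomic coverage: each environment
#' stands alone.
#'
#' @param data Plot-level tibble.
#' @param response Response column name.
#' @param environments Environments to fit (default: all present).
#' @param reuse Result of a previous [blups_method1()] call on another
#'   trait with identical design rows; per-environment fits are reused via
#'   [lme4::refit()].
#' @return Tibble: `environment`, `genotype`, `blup`, `predicted`; the
#'   per-environment fits are attached as attribute `fits`.
#' @export
blups_method1 <- function(data, response, environments = NULL,
                          reuse = NULL) {
  if (is.null(environments)) environments <- sort(unique(data$environment))
  fits <- list()
  rows <- map(environments, function(e) {
    d <- data |> filter(.data$environment == e, !is.na(.data[[response]]))
    if (length(unique(d$replicate)) < 2)
      abort(paste0("environment ", e, " has < 2 replicates"),
            class = "phenosel_validation_error")
    fit <- fit_mixed_model(d, response,
                           random = c("replicate", "block", "genotype"),
                           reuse = attr(reuse, "fits")[[e]])
    fits[[e]] <<- fit
    genotype_blups(fit) |> mutate(environment = e, .before = 1)
  })
  out <- list_rbind(rows)
  attr(out, "fits") <- fits
  out
}

#' Across-environment genotype BLUPs (Method 2)
#'
#' Single REML fit of the full all-random trial model over every
#' environment; unbalanced or missing genotype-environment cells are handled
#' by shrinkage. With one environment the environment terms are inestimable
#' and are dropped, recovering the by-environment model.
#'
#' @param data Plot-level tibble.
#' @param response Response column name.
#' @param reuse Result of a previous [blups_method2()] call on another
#'   trait with identical design rows; the fit is reused via
#'   [lme4::refit()].
#' @return Tibble: `genotype`, `blup`, `predicted`, with the fit attached
#'   as attribute `fit`.
#' @export
blups_method2 <- function(data, response, reuse = NULL) {
  fit <- fit_mixed_model(data |> filter(!is.na(.data[[response]])), response,
                         reuse = attr(reuse, "fit"))
  out <- genotype_blups(fit)
  attr(out, "fit") <- fit
  out
}
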