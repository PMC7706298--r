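#' SNP quality control
#'
#' Applies the standard marker QC sequence: markers with missing rate
#' strictly above `max_missing` are removed; remaining missing codes are
#' imputed with the marker mean; markers with minor allele frequency
#' strictly below `min_maf` (computed after imputation) are removed.
#'
#' @param geno Genotype matrix, codes \{0, 1, 2, NA\}.
#' @param max_missing Maximum tolerated per-marker missing rate (default 0.10).
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @return Numeric matrix of surviving markers (mean-imputed), with
#'   attributes `n_dropped_missing` and `n_dropped_maf`.
#' @export
snp_qc <- function(geno, max_missing = 0.10, min_maf = 0.05) {
  stopifnot(is.matrix(geno))
  miss <- colMeans(is.na(geno))
  keep1 <- miss <= max_missing
  m <- geno[, keep1, drop = FALSE]
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    na_idx <- which(is.na(m), arr.ind = TRUE)
    m[na_idx] <- mu[na_idx[, 2]]
  }
  p <- colMeans(m) / 2
  maf <- pmin(p, 1 - p)
  keep2 <- maf >= min_maf
  out <- m[, keep2, drop = FALSE]
  if (ncol(out) == 0)
    abort("no markers survive QC", class = "phenosel_validation_error")
  attr(out, "n_dropped_missing") <- sum(!keep1)
  attr(out, "n_dropped_maf") <- sum(!keep2)
  out
}

#' Additive genomic relationship matrix (VanRaden)
#'
#' \deqn{A = \frac{W W^\top}{2 \sum_k p_k (1 - p_k)}}
#' with `W` the marker matrix column-centred by twice the observed allele
#' frequency. Under Hardy-Weinberg equilibrium and many markers the mean
#' diagonal is close to 1.
#'
#' @param m Filtered, imputed marker matrix (no missing codes).
#' @return Symmetric genotype-by-genotype matrix with attribute
#'   `allele_freq`.
#' @export
compute_grm <- function(m) {
  stopifnot(is.matrix(m))
  if (ncol(m) < 2)
    abort("GRM needs at least 2 markers", class = "phenosel_validation_error")
  if (anyNA(m))
    abort("marker matrix contains missing codes; run snp_qc() first",
          class = "phenosel_validation_error")
  p <- colMeans(m) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    abort("all markers monomorphic; GRM undefined",
          class = "phenosel_validation_error")
  W <- sweep(m, 2, 2 * p)
  A <- tcrossprod(W) / denom
  attr(A, "allele_freq") <- p
  A
}

# eigen-rotation of a GRM with PSD repair; returns list(U, d)
.grm_eigen <- function(grm, jitter = 1e-8) {
  ev <- eigen((grm + t(grm)) / 2, symmetric = TRUE)
  d <- ev$values
  if (min(d) < -1e-4 * max(abs(d)))
    abort("GRM is not positive semidefinite (even after jitter)",
          class = "phenosel_validation_error")
  list(U = ev$vectors, d = pmax(d, jitter))
}

# restricted log-likelihood of the rotated one-random-term genomic model,
# sigma2_e profiled out; x = U'1, y = U'pheno
.rll_lambda <- function(log_lambda, y, x, d) {
  lambda <- exp(log_lambda)
  v <- lambda * d + 1
  xv <- sum(x^2 / v)
  mu <- sum(x * y / v) / xv
  r <- y - x * mu
  n <- length(y)
  s2e <- sum(r^2 / v) / (n - 1)
  -0.5 * ((n - 1) * log(s2e) + sum(log(v)) + log(xv) + (n - 1))
}

# full restricted LL in (sigma2_g, sigma2_e), for SE computation
.rll_params <- function(s2g, s2e, y, x, d) {
  v <- s2g * d + s2e
  xv <- sum(x^2 / v)
  mu <- sum(x * y / v) / xv
  r <- y - x * mu
  -0.5 * (sum(log(v)) + log(xv) + sum(r^2 / v))
}

#' SNP-based heritability from a genomic relationship matrix
#'
#' Fits, by REML, the one-random-term genomic model
#' \eqn{y = \mu + Zu + \varepsilon} with \eqn{u \sim N(0, A\sigma^2_g)} and
#' computes \eqn{h^2_{SNP} = \sigma^2_g / (\sigma^2_g + \sigma^2_e)}. The
#' phenotype is typically the across-environment (Method 2) genotype BLUP.
#' Computation rotates the model by the eigenvectors of `A`, reducing the
#' restricted likelihood to a one-dimensional profile in the variance ratio;
#' the standard error of \eqn{h^2} comes from the inverse observed
#' information via the delta method.
#'
#' @param values Tibble with columns `genotype` and `value` (or a named
#'   numeric vector).
#' @param grm Genomic relationship matrix with matching row names.
#' @return A `genomic_fit` object with `sigma2_g`, `sigma2_e`, `h2_snp`,
#'   `se_h2`, `mu`.
#' @export
estimate_h2_snp <- function(values, grm) {
  if (is.data.frame(values))
    values <- setNames(values$value, values$genotype)
  ids <- intersect(rownames(grm), names(values))
  if (length(ids) < 10)
    abort("need >= 10 genotypes shared between phenotype and GRM",
          class = "phenosel_validation_error")
  y0 <- values[ids]
  A <- grm[ids, ids]
  eg <- .grm_eigen(A)
  y <- drop(crossprod(eg$U, y0))
  x <- drop(crossprod(eg$U, rep(1, length(y0))))
  opt <- optimize(function(l) -.rll_lambda(l, y, x, eg$d),
                  interval = c(-12, 12))
  lambda <- exp(opt$minimum)
  v <- lambda * eg$d + 1
  xv <- sum(x^2 / v)
  mu <- sum(x * y / v) / xv
  r <- y - x * mu
  s2e <- sum(r^2 / v) / (length(y) - 1)
  s2g <- lambda * s2e
  h2 <- s2g / (s2g + s2e)

  # observed information in (s2g, s2e) by numerical differentiation
  se_h2 <- tryCatch({
    eps <- c(s2g, s2e) * 1e-4 + 1e-10
    f <- function(th) .rll_params(th[1], th[2], y, x, eg$d)
    H <- matrix(0, 2, 2)
    th0 <- c(s2g, s2e)
    for (i in 1:2) for (j in 1:2) {
      ei <- ej <- c(0, 0); ei[i] <- eps[i]; ej[j] <- eps[j]
      H[i, j] <- (f(th0 + ei + ej) - f(th0 + ei - ej) -
                    f(th0 - ei + ej) + f(th0 - ei - ej)) /
        (4 * eps[i] * eps[j])
    }
    Vth <- solve(-H)
    gr <- c(s2e, -s2g) / (s2g + s2e)^2
    sqrt(max(0, drop(t(gr) %*% Vth %*% gr)))
  }, error = function(e) NA_real_)

  structure(list(mu = mu * 1, sigma2_g = s2g, sigma2_e = s2e,
                 h2_snp = h2, se_h2 = se_h2,
                 loglik = -opt$objective, n = length(y)),
            class = "genomic_fit")
}

#' @export
print.genomic_fit <- function(x, ...) {
  cat(sprintf("<genomic_fit> h2_SNP = %.3f (SE %.3f), s2_g = %.4g, s2_e = %.4g, n = %d\n",
              x$h2_snp, x$se_h2, x$sigma2_g, x$sigma2_e, x$n))
  invisible(x)
}

#' @exportS3Method
tidy.genomic_fit <- function(x, ...) {
  tibble(term = c("sigma2_g", "sigma2_e", "h2_snp"),
         estimate = c(x$sigma2_g, x$sigma2_e, x$h2_snp),
         std.error = c(NA, NA, x$se_h2))
}

#' @exportS3Method
glance.genomic_fit <- function(x, ...) {
  tibble(h2_snp = x$h2_snp, se_h2 = x$se_h2, n = x$n, logLik = x$loglik)
}

# negative restricted LL of the rotated bivariate genomic model;
# theta = log-Cholesky of G0 (3) then R0 (3); Y is n x 2 rotated phenotypes
.neg_rll_biv <- function(theta, Y, x, d) {
  Lg <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  Lr <- matrix(c(exp(theta[4]), theta[5], 0, exp(theta[6])), 2, 2)
  G0 <- tcrossprod(Lg)
  R0 <- tcrossprod(Lr)
  n <- nrow(Y)
  Aq <- matrix(0, 2, 2); b <- c(0, 0)
  logdet <- 0
  Sinv <- vector("list", n)
  for (i in seq_len(n)) {
    S <- d[i] * G0 + R0
    det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
    if (!is.finite(det_s) || det_s <= 1e-300) return(1e10)
    Si <- matrix(c(S[2, 2], -S[1, 2], -S[1, 2], S[1, 1]), 2, 2) / det_s
    Sinv[[i]] <- Si
    logdet <- logdet + log(det_s)
    Aq <- Aq + x[i]^2 * Si
    b <- b + x[i] * (Si %*% Y[i, ])
  }
  det_a <- Aq[1, 1] * Aq[2, 2] - Aq[1, 2]^2
  if (!is.finite(det_a) || det_a <= 1e-300) return(1e10)
  mu <- solve(Aq, b)
  quad <- 0
  for (i in seq_len(n)) {
    r <- Y[i, ] - x[i] * drop(mu)
    quad <- quad + drop(t(r) %*% Sinv[[i]] %*% r)
  }
  0.5 * (logdet + quad + log(det_a))
}

#' Genetic correlation between two traits via bivariate genomic REML
#'
#' Fits the two-trait mixed model with genetic covariance
#' \eqn{G_0 \otimes A} and residual covariance \eqn{R_0 \otimes I} by direct
#' restricted-likelihood maximisation over log-Cholesky factors of the 2x2
#' matrices (trait means profiled out by GLS), after eigen-rotation by the
#' GRM. The genetic correlation is
#' \eqn{r_g = G_{0,12} / \sqrt{G_{0,11} G_{0,22}}}, clipped to `[-1, 1]`
#' with a warning if the optimum steps outside.
#'
#' @param trait_a,trait_b Tibbles with `genotype`, `value` (or named
#'   vectors), e.g. Method-2 BLUPs of two traits.
#' @param grm Genomic relationship matrix.
#' @return An `rg_fit` object with `rg`, `se`, `G0`, `R0`.
#' @export
estimate_genetic_correlation <- function(trait_a, trait_b, grm) {
  if (is.data.frame(trait_a)) trait_a <- setNames(trait_a$value, trait_a$genotype)
  if (is.data.frame(trait_b)) trait_b <- setNames(trait_b$value, trait_b$genotype)
  ids <- Reduce(intersect, list(rownames(grm), names(trait_a), names(trait_b)))
  if (length(ids) < 10)
    abort("need >= 10 genotypes shared between both traits and the GRM",
          class = "phenosel_validation_error")
  Y0 <- cbind(trait_a[ids], trait_b[ids])
  # scale traits to unit variance for numerical stability; rg is invariant
  sds <- apply(Y0, 2, sd)
  if (any(sds < 1e-12))
    abort("a trait is constant; genetic correlation undefined",
          class = "phenosel_validation_error")
  Ys <- sweep(Y0, 2, sds, "/")
  eg <- .grm_eigen(grm[ids, ids])
  Y <- crossprod(eg$U, Ys)
  x <- drop(crossprod(eg$U, rep(1, length(ids))))

  # initialise from univariate fits
  uni <- lapply(1:2, function(k)
    estimate_h2_snp(setNames(Ys[, k], ids), grm[ids, ids]))
  g1 <- max(uni[[1]]$sigma2_g, 1e-4); g2 <- max(uni[[2]]$sigma2_g, 1e-4)
  e1 <- max(uni[[1]]$sigma2_e, 1e-4); e2 <- max(uni[[2]]$sigma2_e, 1e-4)
  theta0 <- c(0.5 * log(g1), 0, 0.5 * log(g2),
              0.5 * log(e1), 0, 0.5 * log(e2))
  opt <- optim(theta0, .neg_rll_biv, Y = Y, x = x, d = eg$d,
               method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-10))
  th <- opt$par
  Lg <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)
  Lr <- matrix(c(exp(th[4]), th[5], 0, exp(th[6])), 2, 2)
  G0 <- tcrossprod(Lg); R0 <- tcrossprod(Lr)
  tot <- diag(G0) + diag(R0)
  degenerate <- any(diag(G0) < 1e-6 * tot)
  rg <- if (degenerate) NA_real_ else G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2])
  if (!is.na(rg) && abs(rg) > 1) {
    warn("genetic correlation outside [-1, 1]; clipped")
    rg <- max(min(rg, 1), -1)
  }
  if (degenerate)
    warn("near-zero genetic variance for a trait; r_g undefined")

  # delta-method SE through the numerical Hessian in theta
  se <- tryCatch({
    if (degenerate) NA_real_ else {
      rg_of <- function(t) {
        L <- matrix(c(exp(t[1]), t[2], 0, exp(t[3])), 2, 2)
        G <- tcrossprod(L)
        G[1, 2] / sqrt(G[1, 1] * G[2, 2])
      }
      eps <- pmax(abs(th), 0.1) * 1e-4
      H <- matrix(0, 6, 6)
      for (i in 1:6) for (j in 1:6) {
        ei <- ej <- numeric(6); ei[i] <- eps[i]; ej[j] <- eps[j]
        H[i, j] <- (.neg_rll_biv(th + ei + ej, Y, x, eg$d) -
                      .neg_rll_biv(th + ei - ej, Y, x, eg$d) -
                      .neg_rll_biv(th - ei + ej, Y, x, eg$d) +
                      .neg_rll_biv(th - ei - ej, Y, x, eg$d)) /
          (4 * eps[i] * eps[j])
      }
      gr <- numeric(6)
      for (i in 1:6) {
        ei <- numeric(6); ei[i] <- eps[i]
        gr[i] <- (rg_of(th + ei) - rg_of(th - ei)) / (2 * eps[i])
      }
      Vth <- solve(H)
      sqrt(max(0, drop(t(gr) %*% Vth %*% gr)))
    }
  }, error = function(e) NA_real_)

  # undo the unit-variance scaling for reported covariance components
  D <- diag(sds)
  structure(list(rg = rg, se = se,
                 G0 = D %*% G0 %*% D, R0 = D %*% R0 %*% D,
                 converged = opt$convergence == 0,
                 n = length(ids)),
            class = "rg_fit")
}

#' @export
print.rg_fit <- function(x, ...) {
  cat(sprintf("<rg_fit> r_g = %.3f (SE %s), n = %d\n", x$rg,
              ifelse(is.na(x$se), "NA", sprintf("%.3f", x$se)), x$n))
  invisible(x)
}

#' @exportS3Method
tidy.rg_fit <- function(x, ...) {
  tibble(term = c("rg", "var_g_a", "var_g_b", "cov_g"),
         estimate = c(x$rg, x$G0[1, 1], x$G0[2, 2], x$G0[1, 2]),
         std.error = c(x$se, NA, NA, NA))
}

#' Genetic correlations of yield with every phenomic trait
#'
#' Convenience wrapper running [estimate_genetic_correlation()] of the
#' response against each listed trait column of a genotype-level BLUP table.
#'
#' @param method2 Genotype-level trait table (Method-2 BLUPs), one row per
#'   genotype.
#' @param grm Genomic relationship matrix.
#' @param response Response column (default `"seed_yield"`).
#' @param traits Trait columns to correlate (default: all numeric except the
#'   response).
#' @return Tibble: `trait`, `rg`, `se`.
#' @export
genetic_correlation_table <- function(method2, grm, response = "seed_yield",
                                      traits = NULL) {
  if (is.null(traits)) {
    num <- names(method2)[vapply(method2, is.numeric, logical(1))]
    traits <- setdiff(num, response)
  }
  ya <- setNames(method2[[response]], method2$genotype)
  rows <- map(traits, function(tr) {
    fit <- tryCatch(
      estimate_genetic_correlation(ya, setNames(method2[[tr]], method2$genotype),
                                   grm),
      error = function(e) NULL)
    tibble(trait = tr,
           rg = if (is.null(fit)) NA_real_ else fit$rg,
           se = if (is.null(fit)) NA_real_ else fit$se)
  })
  list_rbind(rows)
}
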