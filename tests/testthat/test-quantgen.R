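test_that("SNP QC applies missingness, imputation and MAF filters in order", {
  set.seed(1)
  n <- 20
  m <- matrix(rbinom(n * 5, 2, 0.5), n,
              dimnames = list(sprintf("g%02d", 1:n), sprintf("m%d", 1:5)))
  m[1:3, 1] <- NA                 # 15% missing -> dropped
  m[, 2] <- 0L                    # monomorphic -> dropped
  m[5, 3] <- NA                   # 5% missing -> imputed
  out <- snp_qc(m)
  expect_false("m1" %in% colnames(out))
  expect_false("m2" %in% colnames(out))
  expect_equal(out[5, "m3"], mean(m[-5, 3]))
  expect_equal(attr(out, "n_dropped_missing"), 1)
  expect_error(snp_qc(matrix(0L, 4, 2)), class = "phenosel_validation_error")
})

test_that("the relationship matrix matches a scalar-by-scalar oracle", {
  m <- matrix(c(0, 1, 2, 1,
                2, 1, 0, 0,
                1, 1, 1, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  A <- compute_grm(m)
  # brute force, element by element
  p <- colMeans(m) / 2
  denom <- 2 * sum(p * (1 - p))
  for (i in 1:3) for (j in 1:3) {
    acc <- 0
    for (k in 1:4) acc <- acc + (m[i, k] - 2 * p[k]) * (m[j, k] - 2 * p[k])
    expect_equal(A[i, j], unname(acc / denom), tolerance = 1e-12)
  }
  expect_equal(A, t(A))
  expect_error(compute_grm(m[, 1, drop = FALSE]),
               class = "phenosel_validation_error")
})

test_that("identical genotypes have relationship equal to self-relationship", {
  m <- matrix(c(0, 1, 2, 1,
                0, 1, 2, 1,
                2, 0, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  A <- compute_grm(m)
  expect_equal(A["a", "b"], A["a", "a"])
})

test_that("the relationship matrix is invariant to marker order and duplication", {
  set.seed(3)
  m <- matrix(rbinom(10 * 50, 2, 0.4), 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:50)))
  A <- compute_grm(m)
  expect_equal(compute_grm(m[, sample(50)]), A[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(compute_grm(cbind(m, m))[, ], A[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("mean diagonal is near 1 for a Hardy-Weinberg panel", {
  cfg <- tiny_config(n_genotypes = 50, n_snps = 5000)
  A <- compute_grm(snp_qc(simulate_genotypes(cfg)))
  expect_gt(mean(diag(A)), 0.95)
  expect_lt(mean(diag(A)), 1.05)
})

test_that("genomic REML agrees with a dense-matrix restricted likelihood oracle", {
  set.seed(8)
  n <- 60; m <- 400
  M <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.9)[rep(1:m, each = n)]), n,
              dimnames = list(sprintf("g%02d", 1:n), sprintf("s%d", 1:m)))
  A <- compute_grm(snp_qc(M))
  cz <- sample(m, 100)
  g <- scale(sweep(M[, cz], 2, colMeans(M[, cz])) %*% rnorm(100))
  y <- setNames(drop(g) + rnorm(n), rownames(M))
  fit <- estimate_h2_snp(y, A)

  # oracle: dense V = s2g*A + s2e*I, REML profile optimised independently
  rll_dense <- function(log_lambda) {
    lam <- exp(log_lambda)
    V <- lam * A + diag(n)
    Vi <- solve(V)
    one <- rep(1, n)
    xv <- drop(t(one) %*% Vi %*% one)
    mu <- drop(t(one) %*% Vi %*% y) / xv
    r <- y - mu
    s2e <- drop(t(r) %*% Vi %*% r) / (n - 1)
    -0.5 * ((n - 1) * log(s2e) + determinant(V)$modulus + log(xv) + (n - 1))
  }
  opt <- optimize(function(l) -rll_dense(l), c(-10, 10))
  lam_oracle <- exp(opt$minimum)
  h2_oracle <- lam_oracle / (lam_oracle + 1)
  expect_equal(fit$h2_snp, h2_oracle, tolerance = 1e-3)
  expect_true(fit$h2_snp >= 0 && fit$h2_snp <= 1)
  expect_true(is.finite(fit$se_h2))
})

test_that("heritability of marker-free noise is estimated near zero", {
  h2 <- vapply(1:3, function(s) {
    set.seed(100 + s)
    n <- 150; m <- 600
    M <- matrix(rbinom(n * m, 2, 0.5), n,
                dimnames = list(sprintf("g%03d", 1:n), sprintf("s%d", 1:m)))
    A <- compute_grm(snp_qc(M))
    estimate_h2_snp(setNames(rnorm(n), rownames(M)), A)$h2_snp
  }, numeric(1))
  expect_lt(median(h2), 0.35)
})

test_that("genetic correlation is 1 for a trait against itself and symmetric", {
  set.seed(12)
  n <- 80; m <- 400
  M <- matrix(rbinom(n * m, 2, 0.5), n,
              dimnames = list(sprintf("g%02d", 1:n), sprintf("s%d", 1:m)))
  A <- compute_grm(snp_qc(M))
  g <- scale(sweep(M, 2, colMeans(M)) %*% rnorm(m))
  ya <- setNames(drop(g) + rnorm(n, 0, 0.8), rownames(M))
  yb <- setNames(drop(g) * -0.8 + rnorm(n, 0, 0.8), rownames(M))
  self <- suppressWarnings(estimate_genetic_correlation(ya, ya + 0, A))
  expect_gt(self$rg, 0.98)
  ab <- suppressWarnings(estimate_genetic_correlation(ya, yb, A))
  ba <- suppressWarnings(estimate_genetic_correlation(yb, ya, A))
  expect_equal(ab$rg, ba$rg, tolerance = 0.02)
  expect_lt(ab$rg, -0.4)
  expect_true(abs(ab$rg) <= 1)
})

test_that("genetic correlation of independent genetic traits is near zero", {
  rgs <- vapply(1:3, function(s) {
    set.seed(300 + s)
    n <- 150; m <- 600
    M <- matrix(rbinom(n * m, 2, 0.5), n,
                dimnames = list(sprintf("g%03d", 1:n), sprintf("s%d", 1:m)))
    A <- compute_grm(snp_qc(M))
    W <- sweep(M, 2, colMeans(M))
    g1 <- scale(W %*% rnorm(m)); g2 <- scale(W %*% rnorm(m))
    ya <- setNames(drop(g1) + rnorm(n), rownames(M))
    yb <- setNames(drop(g2) + rnorm(n), rownames(M))
    suppressWarnings(estimate_genetic_correlation(ya, yb, A))$rg
  }, numeric(1))
  expect_lt(median(abs(rgs)), 0.4)
})

test_that("the correlation table runs over several traits", {
  set.seed(14)
  n <- 60; m <- 300
  M <- matrix(rbinom(n * m, 2, 0.5), n,
              dimnames = list(sprintf("g%02d", 1:n), sprintf("s%d", 1:m)))
  A <- compute_grm(snp_qc(M))
  g <- drop(scale(sweep(M, 2, colMeans(M)) %*% rnorm(m)))
  tbl <- tibble::tibble(genotype = rownames(M),
                        seed_yield = g + rnorm(n, 0, 0.5),
                        VREI2_S1 = -g + rnorm(n, 0, 0.5),
                        CA_S1 = 0.3 * g + rnorm(n))
  out <- suppressWarnings(genetic_correlation_table(tbl, A))
  expect_equal(out$trait, c("VREI2_S1", "CA_S1"))
  expect_lt(out$rg[1], 0)
})
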