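# plain unstructured genotypes: one population, binomial(2, p) per variant
plain_genotypes <- function(n, m, seed) {
  set.seed(seed)
  p <- stats::runif(m, 0.1, 0.9)
  G <- sapply(p, function(pp) stats::rbinom(n, 2, pp))
  rownames(G) <- sprintf("i%03d", seq_len(n))
  G
}

test_that("the GRM equals a brute-force double loop to 1e-10", {
  G <- plain_genotypes(10, 100, seed = 3)
  p <- colMeans(G) / 2
  poly <- p > 0 & p < 1 # variants monomorphic in sample carry no information
  suppressMessages(K <- compute_grm(G))
  G <- G[, poly]
  p <- p[poly]
  n <- nrow(G)
  Kb <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      Kb[i, j] <- mean((G[i, ] - 2 * p) * (G[j, ] - 2 * p) /
                         (2 * p * (1 - p)))
    }
  }
  expect_equal(unname(unclass(K)), Kb, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("a duplicated individual shows twin-level relatedness", {
  G <- plain_genotypes(20, 300, seed = 5)
  G[2, ] <- G[1, ] # clone
  K <- compute_grm(G)
  expect_equal(K[1, 2], K[1, 1], tolerance = 1e-10)
  expect_gt(K[1, 2], 0.8)
})

test_that("unrelated individuals have near-zero off-diagonals with sd ~ 1/sqrt(M)", {
  M <- 400
  G <- plain_genotypes(60, M, seed = 7)
  K <- compute_grm(G)
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 0.02)
  expect_equal(stats::sd(off), 1 / sqrt(M), tolerance = 0.3)
  expect_equal(mean(diag(K)), 1, tolerance = 0.05)
})

test_that("monomorphic variants are excluded and small panels rejected", {
  G <- plain_genotypes(30, 60, seed = 9)
  G[, 1] <- 0
  n_poly <- sum(colMeans(G) > 0 & colMeans(G) < 2)
  expect_message(K <- compute_grm(G), "monomorphic")
  expect_equal(attr(K, "n_variants"), n_poly)
  expect_error(suppressMessages(compute_grm(G[, 1:20])), "at least 50")
})

test_that("PCs are orthonormal, sign-stable, and separate populations", {
  set.seed(11)
  n <- 60
  m <- 300
  pop <- rep(0:1, each = n / 2)
  p1 <- stats::runif(m, 0.1, 0.9)
  p2 <- pmin(pmax(p1 + stats::rnorm(m, 0, 0.18), 0.02), 0.98)
  G <- t(sapply(pop, function(g) {
    stats::rbinom(m, 2, if (g == 0) p1 else p2)
  }))
  rownames(G) <- sprintf("i%02d", 1:n)
  pcs <- top_pcs(G, k = 5)
  U <- sweep(pcs, 2, sqrt(attr(pcs, "values")), "/")
  expect_equal(crossprod(U), diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  expect_gt(abs(stats::cor(pcs[, 1], pop)), 0.9)
  pcs2 <- top_pcs(G, k = 5)
  expect_identical(pcs, pcs2)
  expect_error(top_pcs(G, k = n + 1), "exceeds")
})

test_that("with identity kinship the mixed model reduces to OLS", {
  set.seed(13)
  n <- 60
  G <- plain_genotypes(n, 80, seed = 13)
  dm <- dosage_matrix(
    tibble::tibble(chrom = "1", pos = seq_len(ncol(G)) * 1000,
                   id = colnames(G, do.NULL = FALSE, prefix = "v")),
    G
  )
  y <- stats::rnorm(n)
  covs <- data.frame(c1 = stats::rnorm(n))
  em <- emmax_assoc(y, dm, diag(n), pcs = NULL, covariates = covs)
  v <- attr(em, "variants")
  for (j in c(1, 20, nrow(em))) {
    jj <- match(v$id[j], dm$variants$id)
    o <- oracle_marker_fit(y, dm$dosage[, jj], covs)
    expect_equal(em$beta[j], unname(o["beta"]), tolerance = 1e-6)
    expect_equal(em$p[j], unname(o["p"]), tolerance = 1e-6)
  }
})

test_that("INFO and MAF filters are applied before testing", {
  G <- plain_genotypes(40, 60, seed = 15)
  v <- tibble::tibble(chrom = "1", pos = seq_len(60) * 100,
                      id = paste0("v", 1:60),
                      info = c(0.2, rep(0.9, 59)))
  G[, 2] <- 0 # monomorphic -> maf 0
  dm <- dosage_matrix(v, G)
  y <- stats::rnorm(40)
  em <- emmax_assoc(y, dm, diag(40))
  ids <- attr(em, "variants")$id
  expect_false("v1" %in% ids) # low INFO
  expect_false("v2" %in% ids) # low MAF
  expect_equal(nrow(em), 58)
})

test_that("P-values are invariant to affine rescaling of the outcome", {
  sim <- shared_sim()
  K <- compute_grm(sim$dosages)
  y <- sim$cohort$bmi
  a <- emmax_assoc(y, sim$dosages, K)
  b <- emmax_assoc(3.7 * y + 11, sim$dosages, K)
  expect_equal(-log10(a$p), -log10(b$p), tolerance = 1e-8)
})

test_that("the REML variance ratio is recovered in structured cohorts", {
  # families of 4 siblings; polygenic signal drawn from the realized GRM
  set.seed(17)
  n_fam <- 45
  n <- 4 * n_fam
  m <- 500
  fam <- rep(seq_len(n_fam), each = 4)
  pf <- stats::runif(m, 0.2, 0.8)
  G <- matrix(0, n, m)
  for (f in seq_len(n_fam)) {
    par1 <- cbind(stats::rbinom(m, 1, pf), stats::rbinom(m, 1, pf))
    par2 <- cbind(stats::rbinom(m, 1, pf), stats::rbinom(m, 1, pf))
    for (k in 0:3) {
      G[4 * (f - 1) + k + 1, ] <-
        par1[cbind(seq_len(m), stats::rbinom(m, 1, 0.5) + 1)] +
        par2[cbind(seq_len(m), stats::rbinom(m, 1, 0.5) + 1)]
    }
  }
  rownames(G) <- sprintf("i%03d", seq_len(n))
  K <- compute_grm(G)
  lambda_true <- 1.5
  e <- eigen(K, symmetric = TRUE)
  g <- e$vectors %*% (sqrt(pmax(e$values, 0) * lambda_true) * stats::rnorm(n))
  y <- as.numeric(g) + stats::rnorm(n)
  vc <- admixscan:::emmax_reml(y, K, cbind(rep(1, n)))
  # profile-likelihood 95% interval covers the truth
  dev <- 2 * (vc$loglik - vc$reml_ll(log(lambda_true)))
  expect_lt(dev, stats::qchisq(0.95, 1))
  expect_gt(vc$lambda, 0.3)
})

test_that("regional permutation threshold hits closed forms", {
  set.seed(19)
  n <- 80
  # a single variant: the regional threshold is just the test level
  G1 <- matrix(stats::rbinom(n, 2, 0.5), n, 1,
               dimnames = list(sprintf("i%02d", 1:n), "v1"))
  dm1 <- dosage_matrix(tibble::tibble(chrom = "1", pos = 100, id = "v1"), G1)
  y <- stats::rnorm(n)
  th1 <- regional_threshold(y, dm1, diag(n), n_perm = 400, seed = 20)
  expect_equal(th1$threshold, 0.05, tolerance = 0.35)
  # M independent variants: Sidak
  M <- 12
  G <- sapply(stats::runif(M, 0.3, 0.7), function(p) stats::rbinom(n, 2, p))
  rownames(G) <- rownames(G1)
  dm <- dosage_matrix(
    tibble::tibble(chrom = "1", pos = (1:M) * 100, id = paste0("v", 1:M)), G
  )
  th <- regional_threshold(y, dm, diag(n), n_perm = 600, seed = 21)
  sidak <- 1 - 0.95^(1 / M)
  expect_gt(th$threshold, 0.6 * sidak)
  expect_lt(th$threshold, 1.6 * sidak)
  # seeded reruns are bit-identical
  th2 <- regional_threshold(y, dm, diag(n), n_perm = 600, seed = 21)
  expect_identical(th$min_p, th2$min_p)
})

test_that("the top-variant report flags regional significance", {
  sim <- shared_sim()
  K <- compute_grm(sim$dosages)
  em <- emmax_assoc(sim$cohort$bmi, sim$dosages, K)
  rep1 <- report_top_variant(em, 0.5)
  expect_true(rep1$significant)
  expect_equal(rep1$p, min(em$p, na.rm = TRUE))
  rep2 <- report_top_variant(em, 1e-300)
  expect_false(rep2$significant)
  expect_equal(rep2$or, exp(rep2$beta))
})
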