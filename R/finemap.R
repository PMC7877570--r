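#' Genomic relationship matrix (VanRaden form)
#'
#' Centered, frequency-standardized cross-product of dosages averaged over
#' variants: `K = Z Z' / M` with `Z[ ,j] = (x_j - 2 p_j) / sqrt(2 p_j (1 -
#' p_j))`. Monomorphic variants are excluded with a message. The diagonal is
#' approximately `1 + F` (inbreeding); unrelated individuals have
#' off-diagonals of mean ~0 and s.d. ~`1/sqrt(M)`.
#'
#' @param dosages a [dosage_matrix()] or a plain dosage matrix (individuals x
#'   variants).
#' @param min_variants minimum number of polymorphic variants (default 50).
#' @return symmetric n x n matrix of class `kinship_matrix`, attribute
#'   `n_variants`.
#' @export
compute_grm <- function(dosages, min_variants = 50) {
  X <- if (inherits(dosages, "dosage_matrix")) dosages$dosage else as.matrix(dosages)
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (any(!poly)) message(sum(!poly), " monomorphic variant(s) excluded from GRM")
  if (sum(poly) < min_variants) {
    stop("need at least ", min_variants, " polymorphic variants, got ",
         sum(poly), call. = FALSE)
  }
  Xp <- X[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(sweep(Xp, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(rownames(X), rownames(X))
  structure(K, n_variants = ncol(Z), class = c("kinship_matrix", "matrix", "array"))
}

#' Top principal components of the GRM
#'
#' Eigenvectors of the genomic relationship matrix scaled by the square root
#' of their eigenvalues, with a deterministic sign convention (the
#' largest-magnitude loading of each component is positive).
#'
#' @param dosages a [dosage_matrix()], plain dosage matrix, or a precomputed
#'   `kinship_matrix`.
#' @param k number of components (default 10); must not exceed n.
#' @return n x k matrix of PC scores, eigenvalues as attribute `values`.
#' @export
top_pcs <- function(dosages, k = 10) {
  K <- if (inherits(dosages, "kinship_matrix")) dosages else compute_grm(dosages)
  if (k > nrow(K)) stop("k exceeds the number of individuals", call. = FALSE)
  e <- eigen(K, symmetric = TRUE)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  scores <- sweep(U, 2, sqrt(pmax(e$values[seq_len(k)], 0)), "*")
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(K)
  attr(scores, "values") <- e$values[seq_len(k)]
  scores
}

# REML profile of the variance ratio lambda = sigma_g^2 / sigma_e^2 on the
# eigenbasis of K (EMMA-style). Returns variance components and the rotation
# for reuse in per-variant GLS.
emmax_reml <- function(y, K, X, ridge = 1e-6) {
  n <- length(y)
  K <- as.matrix(K) + diag(ridge, n)
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    stop("kinship matrix not positive semi-definite after ridge", call. = FALSE)
  }
  d <- pmax(e$values, 0)
  U <- e$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  p <- qr(X)$rank
  reml_ll <- function(loglam) {
    lam <- exp(loglam)
    S <- lam * d + 1
    w <- 1 / S
    XtWX <- crossprod(Xs, Xs * w)
    b <- solve(XtWX, crossprod(Xs, ys * w))
    r <- ys - Xs %*% b
    rss <- sum(r^2 * w)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + (n - p) + sum(log(S)) +
              determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(reml_ll, c(-12, 12), maximum = TRUE, tol = 1e-10)
  # keep the boundary (no genetic variance) if it fits as well
  ll0 <- reml_ll(-30)
  lambda <- if (ll0 >= opt$objective - 1e-8) 0 else exp(opt$maximum)
  S <- lambda * d + 1
  w <- 1 / S
  XtWX <- crossprod(Xs, Xs * w)
  b <- solve(XtWX, crossprod(Xs, ys * w))
  rss <- sum((ys - Xs %*% b)^2 * w)
  s2e <- rss / (n - p)
  list(
    lambda = lambda, sigma_g2 = lambda * s2e, sigma_e2 = s2e,
    loglik = max(opt$objective, ll0), U = U, d = d, S = S,
    reml_ll = reml_ll
  )
}

#' EMMAX-style mixed-model single-variant association
#'
#' Two-step linear mixed model: (1) variance components `sigma_g^2 K +
#' sigma_e^2 I` are estimated once by REML under the null (no variant) via a
#' one-dimensional profile over the ratio `lambda = sigma_g^2 / sigma_e^2` on
#' the eigenbasis of the kinship matrix; (2) each variant is tested by
#' generalized least squares with that covariance held fixed, i.e. ordinary
#' least squares in the whitened space with a Wald t-test. Binary traits are
#' analyzed as 0/1 outcomes on the linear scale (standard EMMAX practice).
#' Variants failing the INFO or minor-allele-frequency filter are excluded up
#' front; zero-variance variants yield `NA`.
#'
#' @param y numeric outcome vector (binary traits coded 0/1).
#' @param dosages a [dosage_matrix()] restricted to the candidate region.
#' @param kinship a [compute_grm()] result (or any symmetric PSD matrix).
#' @param pcs matrix of principal-component covariates (e.g. [top_pcs()]),
#'   or `NULL`.
#' @param covariates optional data.frame of additional covariates.
#' @param min_info INFO-score filter (default 0.4).
#' @param min_maf minor-allele-frequency filter (default 0.01).
#' @param ridge diagonal ridge added to the kinship for PSD safety.
#' @return a `scan_result` tibble (one row per retained variant) with
#'   attributes `varcomp` (list: `lambda`, `sigma_g2`, `sigma_e2`, `loglik`)
#'   and `variants` (the retained variant metadata).
#' @export
emmax_assoc <- function(y, dosages, kinship, pcs = NULL, covariates = NULL,
                        min_info = 0.4, min_maf = 0.01, ridge = 1e-6) {
  G <- dosages$dosage
  v <- dosages$variants
  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- v$info >= min_info & maf >= min_maf
  G <- G[, keep, drop = FALSE]
  v <- v[keep, , drop = FALSE]
  X <- cbind(`(Intercept)` = rep(1, length(y)))
  if (!is.null(pcs)) X <- cbind(X, pcs)
  if (!is.null(covariates)) {
    X <- cbind(X, stats::model.matrix(~., data = covariates)[, -1, drop = FALSE])
  }
  # standardize the outcome so results are exactly invariant to affine
  # rescaling of y (betas are mapped back to the input scale)
  y_scale <- stats::sd(y)
  y_center <- mean(y)
  ys <- (y - y_center) / y_scale
  vc <- emmax_reml(ys, kinship, X, ridge = ridge)
  wsq <- 1 / sqrt(vc$S)
  yw <- crossprod(vc$U, ys) * wsq
  Xw <- crossprod(vc$U, X) * matrix(wsq, nrow(X), ncol(X))
  Gw <- crossprod(vc$U, G) * matrix(wsq, nrow(G), ncol(G))
  fs <- fast_linear_scan(yw, Gw, Xw)
  res <- .scan_result(v, fs$beta * y_scale, fs$se * y_scale, fs$p, length(y),
    model = "emmax_lmm", covariates = colnames(X)
  )
  vc$sigma_g2 <- vc$sigma_g2 * y_scale^2
  vc$sigma_e2 <- vc$sigma_e2 * y_scale^2
  attr(res, "varcomp") <- vc[c("lambda", "sigma_g2", "sigma_e2", "loglik")]
  attr(res, "variants") <- v
  res
}

#' Regional significance threshold by residual permutation
#'
#' Permutes the covariate-adjusted residuals of the outcome (adding them back
#' to the fitted covariate values), reruns the mixed-model association on the
#' region for each permutation, collects the regional minimum P-value, and
#' returns its lower `level`-quantile — the regional critical value used to
#' declare a fine-mapped variant significant after accounting for the number
#' of variants tested.
#'
#' @inheritParams emmax_assoc
#' @param n_perm number of permutations (default 1000).
#' @param level quantile (default 0.05).
#' @param seed RNG seed.
#' @return a [threshold_from_min_p()] object.
#' @export
regional_threshold <- function(y, dosages, kinship, pcs = NULL,
                               covariates = NULL, n_perm = 1000, level = 0.05,
                               seed = 1L, min_info = 0.4, min_maf = 0.01) {
  set.seed(seed)
  X <- cbind(rep(1, length(y)))
  if (!is.null(pcs)) X <- cbind(X, pcs)
  if (!is.null(covariates)) {
    X <- cbind(X, stats::model.matrix(~., data = covariates)[, -1, drop = FALSE])
  }
  qrX <- qr(X)
  fitted <- qr.fitted(qrX, y)
  resid <- qr.resid(qrX, y)
  min_p <- numeric(0)
  while (length(min_p) < n_perm) {
    yp <- fitted + sample(resid)
    sc <- emmax_assoc(yp, dosages, kinship, pcs, covariates,
                      min_info = min_info, min_maf = min_maf)
    mp <- suppressWarnings(min(sc$p, na.rm = TRUE))
    if (is.finite(mp)) min_p <- c(min_p, mp) else message("all-NA permutation redrawn")
  }
  threshold_from_min_p(min_p, level)
}

#' Top-variant report for a fine-mapped region
#'
#' Reproduces the reporting rule for candidate regions: the minimum-P variant
#' in the region is reported, flagged significant when its P-value falls
#' below the regional permutation threshold.
#'
#' @param scan an [emmax_assoc()] result.
#' @param regional a [threshold_from_min_p()] object (or numeric threshold).
#' @return one-row tibble: variant coordinates, `beta`, `or` (`exp(beta)`),
#'   `se`, `p`, `significant`.
#' @export
report_top_variant <- function(scan, regional) {
  thr <- if (inherits(regional, "threshold_estimate")) regional$threshold else regional
  j <- which.min(scan$p)
  v <- attr(scan, "variants")
  tibble::tibble(
    id = v$id[j], chrom = scan$chrom[j], pos = scan$pos[j],
    beta = scan$beta[j], or = exp(scan$beta[j]), se = scan$se[j],
    p = scan$p[j], significant = scan$p[j] < thr
  )
}
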