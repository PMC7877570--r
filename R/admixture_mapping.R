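#' @title Genome-wide admixture mapping of local ancestry dosage
#' @name admixture_mapping
#' @description
#' Admixture mapping regresses a trait on the local dosage of one ancestry at
#' every marker while controlling for the global proportions of the other
#' ancestries, exploiting ancestry-linked differences in risk-allele
#' frequency. Significance is calibrated by permutation: genome scans of
#' standard-normal phenotypes give the null distribution of the genome-wide
#' minimum P-value, whose lower 5% quantile is the genome-wide threshold.
NULL

# Fast per-column linear association of Y (n x q) columns against X (n x M)
# columns given shared covariates C (n x p, including intercept), by the
# Frisch-Waugh-Lovell projection: identical beta/se/t to the full multiple
# regression at each (marker, phenotype) pair.
# Returns list of M x q matrices beta, se, p (df = n - p - 1).
fast_linear_scan <- function(Y, X, C) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  C <- as.matrix(C)
  n <- nrow(Y)
  qrC <- qr(C)
  p <- qrC$rank
  df <- n - p - 1
  if (df < 1) stop("not enough observations for the scan", call. = FALSE)
  Yr <- qr.resid(qrC, Y)
  Xr <- qr.resid(qrC, X)
  sxx <- colSums(Xr^2)
  syy <- colSums(Yr^2)
  sxy <- crossprod(Xr, Yr) # M x q
  ok <- sxx > n * 1e-12 * pmax(colMeans(X^2), 1)
  beta <- sweep(sxy, 1, sxx, "/")
  rss <- pmax(outer(rep(1, length(sxx)), syy) - sweep(sxy^2, 1, sxx, "/"), 0)
  se <- sqrt(sweep(rss / df, 1, sxx, "/"))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  beta[!ok, ] <- NA_real_
  se[!ok, ] <- NA_real_
  pval[!ok, ] <- NA_real_
  list(beta = beta, se = se, p = pval, df = df, ok = ok)
}

.scan_result <- function(variants, beta, se, p, n, model, covariates = NULL,
                         conditioning = NULL) {
  structure(
    tibble::tibble(
      chrom = variants$chrom, pos = variants$pos,
      beta = as.numeric(beta), se = as.numeric(se), p = as.numeric(p),
      n = n
    ),
    model = model, covariates = covariates, conditioning = conditioning,
    class = c("scan_result", "tbl_df", "tbl", "data.frame")
  )
}

#' Admixture scan: local ancestry dosage association at every marker
#'
#' At each marker of the local-ancestry marker grid (or the supplied
#' positions), the trait is regressed on the dosage of `ancestry` with the
#' global proportions of the remaining ancestries as covariates (plus any
#' individual-level covariates, which are required for binary traits).
#' Quantitative traits use a vectorized least-squares scan; binary traits fit
#' a per-marker logistic model. Markers with constant or missing-collinear
#' dosage yield `NA` rows.
#'
#' @param y trait vector aligned with `la$individuals` (transformed residual
#'   for quantitative traits; 0/1 for binary).
#' @param la a [local_ancestry_set()].
#' @param ga tibble of global proportions (`id` + ancestry columns).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param ancestry the mapped ancestry (default `"PNS"`).
#' @param covariates optional data.frame of individual-level covariates.
#' @param positions tibble `chrom`,`pos` of test positions (default: the full
#'   marker grid).
#' @param min_posterior tract posterior filter for the dosage (default 0.9).
#' @return a `scan_result` tibble: `chrom`, `pos`, `beta`, `se`, `p`, `n`.
#' @export
admixture_scan <- function(y, la, ga,
                           trait_type = c("quantitative", "binary"),
                           ancestry = "PNS", covariates = NULL,
                           positions = NULL, min_posterior = 0.9) {
  trait_type <- match.arg(trait_type)
  if (stats::var(y, na.rm = TRUE) == 0) stop("trait is constant", call. = FALSE)
  if (is.null(positions)) positions <- la$map[, c("chrom", "pos")]
  D <- local_dosage_at(la, ancestry, positions, min_posterior = min_posterior)
  ctrl <- setdiff(setdiff(names(ga), "id"), ancestry)
  Q <- as.matrix(ga[match(la$individuals, ga$id), ctrl])
  C <- cbind(`(Intercept)` = 1, Q)
  if (!is.null(covariates)) {
    C <- cbind(C, stats::model.matrix(~., data = covariates)[, -1, drop = FALSE])
  }
  keep <- stats::complete.cases(cbind(y, C))
  yk <- y[keep]
  Ck <- C[keep, , drop = FALSE]
  Dk <- D[keep, , drop = FALSE]
  M <- ncol(Dk)
  beta <- se <- pv <- rep(NA_real_, M)
  if (trait_type == "quantitative") {
    full <- !colSums(is.na(Dk))
    if (any(full)) {
      fs <- fast_linear_scan(yk, Dk[, full, drop = FALSE], Ck)
      beta[full] <- fs$beta
      se[full] <- fs$se
      pv[full] <- fs$p
    }
    for (j in which(!full)) {
      cc <- !is.na(Dk[, j])
      if (sum(cc) <= ncol(Ck) + 1 ||
          stats::var(Dk[cc, j]) == 0) next
      fs <- fast_linear_scan(yk[cc], Dk[cc, j, drop = FALSE],
                             Ck[cc, , drop = FALSE])
      beta[j] <- fs$beta
      se[j] <- fs$se
      pv[j] <- fs$p
    }
  } else {
    for (j in seq_len(M)) {
      cc <- !is.na(Dk[, j])
      d <- Dk[cc, j]
      if (sum(cc) <= ncol(Ck) + 1 || stats::var(d) == 0) next
      fit <- suppressWarnings(
        stats::glm.fit(cbind(d = d, Ck[cc, , drop = FALSE]), yk[cc],
                       family = stats::binomial())
      )
      if (any(is.na(fit$coefficients))) next
      # Wald from the weighted cross-product
      W <- fit$weights
      Xj <- cbind(d = d, Ck[cc, , drop = FALSE])
      V <- tryCatch(solve(crossprod(Xj * sqrt(W))), error = function(e) NULL)
      if (is.null(V)) next
      beta[j] <- fit$coefficients[1]
      se[j] <- sqrt(V[1, 1])
      pv[j] <- 2 * stats::pnorm(-abs(beta[j] / se[j]))
    }
  }
  .scan_result(positions, beta, se, pv, sum(keep),
    model = paste0("admixture_", trait_type),
    covariates = colnames(C)
  )
}

#' Threshold estimate from permutation minima
#'
#' @param min_p numeric vector of per-permutation genome-wide minimum
#'   P-values.
#' @param level target family-wise level (default 0.05).
#' @return object of class `threshold_estimate`: the lower `level`-quantile
#'   of the minima, the minima themselves, and the quantile used.
#' @export
threshold_from_min_p <- function(min_p, level = 0.05) {
  structure(
    list(
      threshold = unname(stats::quantile(min_p, level, type = 1)),
      n_permutations = length(min_p),
      min_p = min_p,
      level = level
    ),
    class = "threshold_estimate"
  )
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "<threshold_estimate> %.3g (lower %g%% quantile of %d permutation minima)\n",
    x$threshold, 100 * x$level, x$n_permutations
  ))
  invisible(x)
}

#' Permutation-calibrated genome-wide significance threshold
#'
#' Runs `n_perm` genome-wide admixture scans, each on a phenotype drawn
#' independently from a standard normal (independent of all genotype and
#' ancestry data), records the genome-wide minimum P-value of each scan, and
#' returns the lower `level`-quantile of those minima. This controls the
#' family-wise error of the scan at `level` given the actual correlation
#' structure of local ancestry. Scans producing no finite P-value are
#' rejected and redrawn (with a message).
#'
#' @param la a [local_ancestry_set()].
#' @param ga tibble of global proportions.
#' @param n_perm number of permutations (at least 100).
#' @param level quantile of the min-P distribution (default 0.05).
#' @param seed RNG seed.
#' @param ancestry the mapped ancestry.
#' @param min_posterior tract posterior filter.
#' @return a [threshold_from_min_p()] object.
#' @export
permutation_threshold <- function(la, ga, n_perm = 1000, level = 0.05,
                                  seed = 1L, ancestry = "PNS",
                                  min_posterior = 0.9) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  set.seed(seed)
  D <- local_dosage_at(la, ancestry, la$map[, c("chrom", "pos")],
                       min_posterior = min_posterior)
  ctrl <- setdiff(setdiff(names(ga), "id"), ancestry)
  C <- cbind(1, as.matrix(ga[match(la$individuals, ga$id), ctrl]))
  cc <- stats::complete.cases(C)
  ok_mark <- !colSums(is.na(D[cc, , drop = FALSE]))
  Dk <- D[cc, ok_mark, drop = FALSE]
  Ck <- C[cc, , drop = FALSE]
  n <- nrow(Dk)
  min_p <- numeric(0)
  while (length(min_p) < n_perm) {
    todo <- n_perm - length(min_p)
    Y <- matrix(stats::rnorm(n * todo), n, todo)
    fs <- fast_linear_scan(Y, Dk, Ck)
    mp <- apply(fs$p, 2, function(col) suppressWarnings(min(col, na.rm = TRUE)))
    bad <- !is.finite(mp)
    if (any(bad)) message(sum(bad), " all-NA permutation scan(s) redrawn")
    min_p <- c(min_p, mp[!bad])
  }
  threshold_from_min_p(min_p[seq_len(n_perm)], level)
}

#' Signal and broad regions from a genome scan
#'
#' A signal region is a maximal run of consecutive markers whose P-value is
#' strictly below the genome-wide threshold; its boundaries are the first and
#' last such marker's position. The broad region extends the signal region
#' through nearby suggestive markers (`-log10 P > broad_neglog10`) within
#' `flank_mb` of the growing region, merging qualifying suggestive segments
#' that lie within `flank_mb` of each other. Each signal region is nested in
#' its broad region, and the peak `-log10 P` is recorded.
#'
#' @param scan a `scan_result` (must be position-sorted within chromosome).
#' @param gw_threshold genome-wide significance threshold (P scale), either a
#'   number or a `threshold_estimate`.
#' @param broad_neglog10 suggestive `-log10 P` cutoff for the broad region
#'   (default 4).
#' @param flank_mb maximum flank/merge distance in megabases (default 5).
#' @return tibble of class `region_set`: `chrom`, `start_bp`, `stop_bp`,
#'   `kind` (`"signal"`/`"broad"`), `peak_neglog10p`, `region_id`.
#' @export
define_regions <- function(scan, gw_threshold, broad_neglog10 = 4,
                           flank_mb = 5) {
  if (inherits(gw_threshold, "threshold_estimate")) {
    gw_threshold <- gw_threshold$threshold
  }
  for (ch in unique(scan$chrom)) {
    if (is.unsorted(scan$pos[scan$chrom == ch])) {
      stop("scan not sorted by position on chromosome ", ch, call. = FALSE)
    }
  }
  flank_bp <- flank_mb * 1e6
  out <- list()
  rid <- 0L
  for (ch in unique(scan$chrom)) {
    s <- scan[scan$chrom == ch, ]
    p <- s$p
    sig <- !is.na(p) & p < gw_threshold
    if (!any(sig)) next
    sug <- !is.na(p) & -log10(p) > broad_neglog10
    # single-linkage clusters of suggestive markers within flank_bp
    sug_pos <- s$pos[sug]
    cl <- cumsum(c(1, diff(sug_pos) > flank_bp))
    runs <- rle(sig)
    ends <- cumsum(runs$lengths)
    starts <- c(1, ends[-length(ends)] + 1)
    for (r in which(runs$values)) {
      rid <- rid + 1L
      i0 <- starts[r]
      i1 <- ends[r]
      sig_start <- s$pos[i0]
      sig_stop <- s$pos[i1]
      peak <- max(-log10(p[i0:i1]))
      # broad region: the suggestive cluster containing this signal run
      memb <- cl[match(sig_start, sug_pos)]
      if (is.na(memb)) { # threshold looser than the suggestive cutoff
        b_start <- sig_start
        b_stop <- sig_stop
      } else {
        b_start <- min(sig_start, sug_pos[cl == memb])
        b_stop <- max(sig_stop, sug_pos[cl == memb])
      }
      peak_b <- max(-log10(p[!is.na(p) & s$pos >= b_start & s$pos <= b_stop]),
                    na.rm = TRUE)
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch,
        start_bp = c(sig_start, b_start), stop_bp = c(sig_stop, b_stop),
        kind = c("signal", "broad"),
        peak_neglog10p = c(peak, peak_b),
        region_id = rid
      )
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(
      chrom = character(), start_bp = numeric(), stop_bp = numeric(),
      kind = character(), peak_neglog10p = numeric(), region_id = integer()
    )
  }
  structure(res, class = c("region_set", class(res)))
}

#' Conditional admixture scan within a region
#'
#' Reruns the admixture scan restricted to a region with the dosages of one
#' or more conditioning variants appended to the covariates. Conditioning
#' columns that are duplicated or collinear with the existing covariates are
#' dropped with a warning.
#'
#' @inheritParams admixture_scan
#' @param conditioning numeric matrix (individuals x conditioning variants)
#'   of dosages, rows aligned with `la$individuals`, or a vector.
#' @param region one-row region (e.g. a row of a [define_regions()] result)
#'   with `chrom`, `start_bp`, `stop_bp`; `NULL` scans all markers.
#' @return a `scan_result` restricted to the region.
#' @export
conditional_scan <- function(y, la, ga, conditioning, region = NULL,
                             trait_type = c("quantitative", "binary"),
                             ancestry = "PNS", covariates = NULL,
                             min_posterior = 0.9) {
  trait_type <- match.arg(trait_type)
  conditioning <- as.matrix(conditioning)
  if (is.null(colnames(conditioning))) {
    colnames(conditioning) <- paste0("cond", seq_len(ncol(conditioning)))
  }
  ctrl <- setdiff(setdiff(names(ga), "id"), ancestry)
  base <- cbind(1, as.matrix(ga[match(la$individuals, ga$id), ctrl]))
  if (!is.null(covariates)) {
    base <- cbind(base, stats::model.matrix(~., data = covariates)[, -1, drop = FALSE])
  }
  keepcols <- logical(ncol(conditioning))
  cur <- base
  for (j in seq_len(ncol(conditioning))) {
    cand <- cbind(cur, conditioning[, j])
    if (qr(cand[stats::complete.cases(cand), , drop = FALSE])$rank > qr(cur[stats::complete.cases(cur), , drop = FALSE])$rank) {
      keepcols[j] <- TRUE
      cur <- cand
    } else {
      warning("conditioning variant ", colnames(conditioning)[j],
              " collinear with existing covariates; dropped", call. = FALSE)
    }
  }
  conditioning <- conditioning[, keepcols, drop = FALSE]
  positions <- la$map[, c("chrom", "pos")]
  if (!is.null(region)) {
    positions <- positions[positions$chrom == region$chrom[1] &
      positions$pos >= region$start_bp[1] &
      positions$pos <= region$stop_bp[1], ]
  }
  covs <- as.data.frame(conditioning)
  if (!is.null(covariates)) covs <- cbind(as.data.frame(covariates), covs)
  res <- admixture_scan(y, la, ga,
    trait_type = trait_type, ancestry = ancestry,
    covariates = covs, positions = positions, min_posterior = min_posterior
  )
  attr(res, "conditioning") <- colnames(conditioning)
  res
}

#' Manhattan-style scan plot
#'
#' @param scan a `scan_result`.
#' @param threshold optional genome-wide threshold (P scale) drawn as a line.
#' @return a ggplot object.
#' @export
plot_scan <- function(scan, threshold = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  d <- tibble::as_tibble(scan)
  d$neglog10p <- -log10(d$p)
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos / 1e6, y = .data$neglog10p)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10] * P)) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    if (inherits(threshold, "threshold_estimate")) threshold <- threshold$threshold
    g <- g + ggplot2::geom_hline(yintercept = -log10(threshold), linetype = 2)
  }
  g
}
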