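#' nSL: haplotype-length statistic for recent positive selection
#'
#' For a focal biallelic site on a phased haplotype panel, nSL contrasts the
#' mean pairwise haplotype-sharing length (counted in markers, not genetic
#' distance) between carriers of the derived allele and carriers of the
#' ancestral allele. For every pair of haplotypes within a class, the length
#' is the number of consecutive markers containing the focal site over which
#' the two haplotypes are identical, capped at `max_extend` markers in each
#' direction and at the panel edges. The default sign convention is
#' `log(mean derived length / mean ancestral length)`, so positive values
#' mean the derived allele sits on the longer shared haplotypes (the
#' footprint of a recent sweep on the derived allele); set `sign_convention =
#' "ancestral"` for the opposite orientation.
#'
#' @param haps binary matrix, haplotypes in rows, markers in columns
#'   (0 = ancestral, 1 = derived); no missing values in the focal window.
#' @param focal column index of the focal variant.
#' @param max_extend cap on the sharing length, in markers per direction
#'   (default 100, the common scan default).
#' @param sign_convention `"derived"` (default) or `"ancestral"`.
#' @return unstandardized nSL value; `NA` when either allele class has fewer
#'   than 2 haplotypes.
#' @export
compute_nsl <- function(haps, focal, max_extend = 100,
                        sign_convention = c("derived", "ancestral")) {
  sign_convention <- match.arg(sign_convention)
  haps <- as.matrix(haps)
  if (!all(haps %in% c(0, 1))) stop("haplotypes must be 0/1", call. = FALSE)
  alleles <- haps[, focal]
  if (length(unique(alleles)) < 2) {
    stop("focal variant is monomorphic", call. = FALSE)
  }
  mean_len <- function(H) {
    k <- nrow(H)
    if (k < 2) return(NA_real_)
    m <- ncol(H)
    lo_cap <- max(1, focal - max_extend)
    hi_cap <- min(m, focal + max_extend)
    tot <- 0
    for (a in 1:(k - 1)) {
      for (b in (a + 1):k) {
        mism <- which(H[a, ] != H[b, ])
        left <- mism[mism < focal]
        right <- mism[mism > focal]
        lo <- max(lo_cap, if (length(left)) max(left) + 1 else 1)
        hi <- min(hi_cap, if (length(right)) min(right) - 1 else m)
        tot <- tot + (hi - lo + 1)
      }
    }
    tot / (k * (k - 1) / 2)
  }
  sl_d <- mean_len(haps[alleles == 1, , drop = FALSE])
  sl_a <- mean_len(haps[alleles == 0, , drop = FALSE])
  if (is.na(sl_d) || is.na(sl_a)) return(NA_real_)
  if (sign_convention == "derived") log(sl_d / sl_a) else log(sl_a / sl_d)
}

#' Derived allele frequency difference between two cohorts
#'
#' @param f_a,f_b derived allele frequencies in `[0,1]`.
#' @return `f_a - f_b`.
#' @export
af_difference <- function(f_a, f_b) {
  stopifnot(all(f_a >= 0 & f_a <= 1), all(f_b >= 0 & f_b <= 1))
  f_a - f_b
}

#' Empirical P-value against a matched null set
#'
#' Compares a focal variant's statistic to all other variants whose derived
#' allele frequency and imputation INFO score fall inside the given matching
#' windows — the standard guard against frequency- and
#' imputation-quality-dependence of haplotype statistics. The estimator is
#' `(r + 1) / (n + 1)` with `r` the number of matched-null statistics at
#' least as extreme as the focal value in the chosen tail, so the P-value is
#' never zero.
#'
#' @param stats tibble with columns `daf`, `info`, `statistic` (one row per
#'   variant), the focal variant included.
#' @param focal row index of the focal variant in `stats`.
#' @param daf_window length-2 numeric, inclusive DAF matching window.
#' @param info_window length-2 numeric, inclusive INFO matching window.
#' @param tail `"upper"` (large statistics extreme) or `"lower"`.
#' @param min_matched minimum size of the matched set (default 100).
#' @return object of class `matched_null`: list with the focal value, the
#'   windows, the matched statistics and the empirical `p`.
#' @export
matched_null_empirical_p <- function(stats, focal, daf_window, info_window,
                                     tail = c("upper", "lower"),
                                     min_matched = 100) {
  tail <- match.arg(tail)
  stopifnot(all(c("daf", "info", "statistic") %in% names(stats)))
  x0 <- stats$statistic[focal]
  in_win <- stats$daf >= daf_window[1] & stats$daf <= daf_window[2] &
    stats$info >= info_window[1] & stats$info <= info_window[2] &
    !is.na(stats$statistic)
  in_win[focal] <- FALSE
  null <- stats$statistic[in_win]
  if (length(null) < min_matched) {
    stop("only ", length(null), " matched variants (need at least ",
         min_matched, ")", call. = FALSE)
  }
  r <- if (tail == "upper") sum(null >= x0) else sum(null <= x0)
  structure(
    list(
      focal = focal, focal_statistic = x0,
      daf_window = daf_window, info_window = info_window,
      n_matched = length(null), null_statistics = null, tail = tail,
      p = (r + 1) / (length(null) + 1)
    ),
    class = "matched_null"
  )
}

#' @export
print.matched_null <- function(x, ...) {
  cat(sprintf(
    "<matched_null> focal statistic %.4g vs %d matched variants (%s tail): empirical P = %.4g\n",
    x$focal_statistic, x$n_matched, x$tail, x$p
  ))
  invisible(x)
}

#' Frequency-bin standardization of nSL values
#'
#' Haplotype length depends strongly on allele frequency, so raw nSL values
#' are standardized within derived-allele-frequency bins: equal-width bins
#' over the observed DAF range (default 50), bins with fewer than
#' `min_per_bin` values merged into their left neighbour, then a z-score
#' within each bin. A constant bin yields z = 0 with a warning.
#'
#' @param values numeric nSL values.
#' @param dafs derived allele frequencies, same length.
#' @param n_bins number of initial bins (default 50).
#' @param min_per_bin minimum occupancy before merging (default 20).
#' @return numeric vector of z-scores; attribute `bin` gives the final bin
#'   index per value.
#' @export
standardize_nsl <- function(values, dafs, n_bins = 50, min_per_bin = 20) {
  stopifnot(length(values) == length(dafs))
  br <- seq(min(dafs), max(dafs), length.out = n_bins + 1)
  bin <- cut(dafs, breaks = br, include.lowest = TRUE, labels = FALSE)
  # merge under-occupied bins leftward (the first bin merges rightward)
  repeat {
    tab <- table(factor(bin, levels = sort(unique(bin))))
    small <- names(tab)[tab < min_per_bin]
    if (!length(small)) break
    b <- as.integer(small[1])
    lev <- sort(unique(bin))
    i <- match(b, lev)
    target <- if (i > 1) lev[i - 1] else lev[i + 1]
    if (is.na(target)) break # single bin left
    bin[bin == b] <- target
  }
  z <- rep(NA_real_, length(values))
  for (b in sort(unique(bin))) {
    i <- which(bin == b)
    v <- values[i]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) {
      warning("constant nSL bin; z set to 0", call. = FALSE)
      z[i] <- 0
    } else {
      z[i] <- (v - mean(v)) / s
    }
  }
  attr(z, "bin") <- bin
  z
}
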