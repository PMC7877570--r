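# Shared fixtures, built in code.

# Hand-built two-individual panel on one 10 Mb chromosome (constant 1 cM/Mb):
# ind A is PNS on both haplotypes; ind B is PNS on hap 1 and EUR on hap 2.
tiny_la <- function(posterior_b = 1.0) {
  map <- constant_rate_map(c(`1` = 1e7), markers_per_chrom = 11)
  tracts <- tibble::tibble(
    individual = c("A", "A", "B", "B"),
    haplotype = c(1L, 2L, 1L, 2L),
    chrom = "1",
    spos = 1, epos = 1e7,
    ancestry = c("PNS", "PNS", "PNS", "EUR"),
    posterior = c(1, 1, 1, posterior_b)
  )
  local_ancestry_set(tracts, map)
}

# small shared simulated cohort reused across test files
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_individuals = 120, n_variants = 150,
        map = constant_rate_map(c(`1` = 5e7, `2` = 5e7), 250),
        seed = 42
      )
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})

# independent per-marker regression oracle: plain lm() at one marker
oracle_marker_fit <- function(y, d, covar) {
  df <- data.frame(y = y, d = d, covar)
  fit <- stats::lm(y ~ ., data = df)
  cf <- summary(fit)$coefficients
  c(beta = cf["d", 1], se = cf["d", 2], p = cf["d", 4])
}

# independent oracle: marker-by-marker outward walk for one haplotype pair
oracle_pair_len <- function(h1, h2, focal, max_extend) {
  m <- length(h1)
  lo <- focal
  while (lo > 1 && lo > focal - max_extend && h1[lo - 1] == h2[lo - 1]) {
    lo <- lo - 1
  }
  hi <- focal
  while (hi < m && hi < focal + max_extend && h1[hi + 1] == h2[hi + 1]) {
    hi <- hi + 1
  }
  hi - lo + 1
}

oracle_nsl <- function(haps, focal, max_extend = 100) {
  cls <- haps[, focal]
  avg <- function(H) {
    k <- nrow(H)
    tot <- 0
    for (a in 1:(k - 1)) {
      for (b in (a + 1):k) {
        tot <- tot + oracle_pair_len(H[a, ], H[b, ], focal, max_extend)
      }
    }
    tot / choose(k, 2)
  }
  log(avg(haps[cls == 1, , drop = FALSE]) / avg(haps[cls == 0, , drop = FALSE]))
}
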