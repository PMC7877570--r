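test_that("scan coefficients match per-marker lm() to 1e-8", {
  cfg <- sim_config(n_individuals = 50, seed = 23,
                    map = constant_rate_map(c(`1` = 5e7), 20))
  la <- simulate_local_ancestry(cfg)
  ga <- compute_global_ancestry(la)
  set.seed(24)
  y <- 0.3 * local_dosage_at(la, "PNS", la$map[3, c("chrom", "pos")])[, 1] +
    stats::rnorm(50)
  scan <- admixture_scan(y, la, ga)
  D <- local_dosage_at(la, "PNS", la$map[, c("chrom", "pos")])
  covar <- as.data.frame(ga[, c("EUR", "EAS", "AFR")])
  for (j in seq_len(20)) {
    o <- oracle_marker_fit(y, D[, j], covar)
    expect_equal(scan$beta[j], unname(o["beta"]), tolerance = 1e-8)
    expect_equal(scan$se[j], unname(o["se"]), tolerance = 1e-8)
    expect_equal(scan$p[j], unname(o["p"]), tolerance = 1e-8)
  }
})

test_that("dosage collinear with the covariate span yields NA", {
  # individuals with homogeneous haplotypes: at every marker the PNS dosage
  # equals 2 * q_PNS, which lies in the span of {1, q_EUR, q_EAS, q_AFR}
  map <- constant_rate_map(c(`1` = 1e7), 5)
  anc <- c("PNS", "PNS", "EUR", "PNS", "EAS", "EUR", "PNS", "EUR",
           "PNS", "EAS", "EUR", "EUR", "EAS", "EAS", "PNS", "AFR")
  tr <- tibble::tibble(
    individual = rep(sprintf("i%d", 1:8), each = 2),
    haplotype = rep(1:2, 8), chrom = "1", spos = 1, epos = 1e7,
    ancestry = anc, posterior = 1
  )
  la <- local_ancestry_set(tr, map)
  ga <- compute_global_ancestry(la)
  set.seed(1)
  y <- stats::rnorm(8)
  scan <- admixture_scan(y, la, ga)
  expect_true(all(is.na(scan$beta)))
  expect_error(admixture_scan(rep(1, 8), la, ga), "constant")
})

test_that("null phenotypes give uniform P-values", {
  # markers within a scan are correlated through shared ancestry tracts, so
  # uniformity is checked at two distant (near-independent) markers across
  # independent phenotype replicates
  sim <- shared_sim()
  ga <- compute_global_ancestry(sim$la)
  set.seed(77)
  take <- c(1, 500) # first marker of chr 1, last of chr 2
  pvals <- unlist(lapply(1:150, function(i) {
    y <- stats::rnorm(length(sim$la$individuals))
    admixture_scan(y, sim$la, ga,
                   positions = sim$la$map[take, c("chrom", "pos")])$p
  }))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("binary scans agree with per-marker glm()", {
  cfg <- sim_config(n_individuals = 120, seed = 33,
                    map = constant_rate_map(c(`1` = 5e7), 10))
  la <- simulate_local_ancestry(cfg)
  ga <- compute_global_ancestry(la)
  set.seed(34)
  y <- stats::rbinom(120, 1, 0.3)
  scan <- admixture_scan(y, la, ga, trait_type = "binary")
  D <- local_dosage_at(la, "PNS", la$map[, c("chrom", "pos")])
  for (j in c(1, 5, 10)) {
    d <- data.frame(y = y, d = D[, j], ga[, c("EUR", "EAS", "AFR")])
    fit <- stats::glm(y ~ ., data = d, family = stats::binomial())
    cf <- summary(fit)$coefficients
    expect_equal(scan$beta[j], unname(cf["d", 1]), tolerance = 1e-6)
    expect_equal(scan$p[j], unname(cf["d", 4]), tolerance = 1e-5)
  }
})

test_that("the threshold is the lower quantile of the min-P list", {
  th <- threshold_from_min_p(0.01 * (1:100), level = 0.05)
  expect_equal(th$threshold, 0.05)
  expect_equal(th$n_permutations, 100)
  expect_error(permutation_threshold(tiny_la(), NULL, n_perm = 10), "n_perm")
})

test_that("with near-independent markers the threshold approaches Sidak", {
  # huge switch rate: tracts much shorter than marker spacing, so marker
  # dosages are nearly independent across the genome
  cfg <- sim_config(
    n_individuals = 150, generations = 400,
    map = constant_rate_map(c(`1` = 5e7), 40), seed = 41
  )
  la <- simulate_local_ancestry(cfg)
  ga <- attr(la, "q_true")
  th <- permutation_threshold(la, ga, n_perm = 1000, seed = 42)
  sidak <- 1 - (1 - 0.05)^(1 / 40)
  expect_gt(th$threshold, 0.8 * sidak)
  expect_lt(th$threshold, 1.25 * sidak)
})

test_that("stronger marker correlation gives a looser (larger) threshold", {
  thr_at_g <- function(g) {
    cfg <- sim_config(
      n_individuals = 150, generations = g,
      map = constant_rate_map(c(`1` = 5e7), 40), seed = 43
    )
    la <- simulate_local_ancestry(cfg)
    permutation_threshold(la, attr(la, "q_true"), n_perm = 400,
                          seed = 44)$threshold
  }
  expect_gte(thr_at_g(3), thr_at_g(300))
})

test_that("regions from a toy peak match hand enumeration", {
  neglog <- c(1, 5, 6, 5, 1)
  scan <- structure(
    tibble::tibble(chrom = "6", pos = (1:5) * 1e6, beta = 0, se = 1,
                   p = 10^(-neglog), n = 10),
    class = c("scan_result", "tbl_df", "tbl", "data.frame")
  )
  rs <- define_regions(scan, gw_threshold = 10^-4.65)
  sig <- rs[rs$kind == "signal", ]
  expect_equal(nrow(sig), 1)
  expect_equal(sig$start_bp, 2e6)
  expect_equal(sig$stop_bp, 4e6)
  expect_equal(sig$peak_neglog10p, 6)
  broad <- rs[rs$kind == "broad", ]
  expect_true(broad$start_bp <= sig$start_bp && broad$stop_bp >= sig$stop_bp)
})

test_that("no significant marker yields an empty region set; singletons collapse", {
  scan <- structure(
    tibble::tibble(chrom = "1", pos = (1:5) * 1e6, beta = 0, se = 1,
                   p = rep(0.5, 5), n = 10),
    class = c("scan_result", "tbl_df", "tbl", "data.frame")
  )
  expect_equal(nrow(define_regions(scan, 1e-5)), 0)
  scan$p[3] <- 1e-6
  rs <- define_regions(scan, 1e-5)
  sig <- rs[rs$kind == "signal", ]
  expect_equal(sig$start_bp, sig$stop_bp)
  expect_equal(sig$start_bp, 3e6)
  # unsorted scans are refused
  expect_error(define_regions(scan[c(2, 1, 3:5), ], 1e-5), "sorted")
})

test_that("regions match a brute-force enumeration on random scans", {
  # independent oracle: direct run/cluster enumeration over index vectors
  oracle_regions <- function(pos, p, thr, broad_nl = 4, flank = 5e6) {
    sig <- which(p < thr)
    if (!length(sig)) return(NULL)
    runs <- split(sig, cumsum(c(1, diff(sig) != 1)))
    sug <- which(-log10(p) > broad_nl)
    lapply(runs, function(r) {
      lo <- min(pos[r]); hi <- max(pos[r])
      repeat {
        grow <- sug[pos[sug] >= lo - flank & pos[sug] <= hi + flank]
        nlo <- min(c(lo, pos[grow])); nhi <- max(c(hi, pos[grow]))
        if (nlo == lo && nhi == hi) break
        lo <- nlo; hi <- nhi
      }
      c(sig_lo = min(pos[r]), sig_hi = max(pos[r]), b_lo = lo, b_hi = hi)
    })
  }
  set.seed(55)
  for (rep in 1:20) {
    pos <- sort(sample(1:2e7, 60))
    p <- 10^-stats::runif(60, 0, 6)
    scan <- structure(
      tibble::tibble(chrom = "2", pos = pos, beta = 0, se = 1, p = p, n = 5),
      class = c("scan_result", "tbl_df", "tbl", "data.frame")
    )
    thr <- 10^-4.65
    rs <- define_regions(scan, thr)
    orc <- oracle_regions(pos, p, thr)
    sig <- rs[rs$kind == "signal", ]
    broad <- rs[rs$kind == "broad", ]
    if (is.null(orc)) {
      expect_equal(nrow(rs), 0)
      next
    }
    expect_equal(nrow(sig), length(orc))
    for (k in seq_along(orc)) {
      expect_equal(sig$start_bp[k], unname(orc[[k]]["sig_lo"]))
      expect_equal(sig$stop_bp[k], unname(orc[[k]]["sig_hi"]))
      expect_equal(broad$start_bp[k], unname(orc[[k]]["b_lo"]))
      expect_equal(broad$stop_bp[k], unname(orc[[k]]["b_hi"]))
    }
    # idempotence: recomputing on the same scan gives the same regions
    expect_equal(define_regions(scan, thr), rs)
  }
})

test_that("conditioning drops duplicated columns and leaves unrelated peaks", {
  sim <- shared_sim()
  ga <- compute_global_ancestry(sim$la)
  set.seed(66)
  n <- length(sim$la$individuals)
  y <- stats::rnorm(n)
  v <- stats::rbinom(n, 2, 0.4)
  cond <- cbind(a = v, b = v) # duplicated column
  expect_warning(
    scan <- conditional_scan(y, sim$la, ga, cond),
    "collinear.*dropped"
  )
  expect_equal(attr(scan, "conditioning"), "a")
  # conditioning on an independent variant barely moves the scan
  plain <- admixture_scan(y, sim$la, ga)
  ok <- !is.na(plain$p) & !is.na(scan$p) & plain$p < 0.5
  rel <- abs(log10(scan$p[ok]) - log10(plain$p[ok])) / abs(log10(plain$p[ok]))
  expect_lt(stats::median(rel), 0.10)
})
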