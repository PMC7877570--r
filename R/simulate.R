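#' Simulation configuration for a synthetic admixed cohort
#'
#' Describes the generative model used throughout the test suite: global
#' ancestry proportions drawn from a Dirichlet, ancestry-switch points placed
#' as a Poisson process along the genetic map (the standard pulse-admixture
#' tract model), ancestry-specific allele frequencies, and phenotypes driven
#' by global ancestry, an optional local causal locus or variant, and
#' SES-like covariates with census-tract clustering.
#'
#' The defaults emulate the study conditions this package targets: a four-way
#' admixed cohort (PNS/EUR/EAS/AFR) with mean proportions close to
#' (0.40, 0.30, 0.29, 0.01), about ten generations since admixture, and a
#' constant 1 cM/Mb map over 2 chromosomes x 50 Mb with 1,000 markers each.
#'
#' @param n_individuals cohort size.
#' @param ancestries ancestry labels; the first is the mapped ancestry.
#' @param dirichlet_alpha positive Dirichlet concentration parameters, one per
#'   ancestry. The total concentration controls the spread of individual
#'   proportions around the mean `alpha / sum(alpha)`.
#' @param generations switch rate per Morgan per haplotype (generations since
#'   the admixture pulse).
#' @param map a [genomic_map()].
#' @param n_variants number of simulated variants (placed uniformly at marker
#'   positions).
#' @param fst Balding-Nichols differentiation used when drawing
#'   ancestry-specific allele frequencies.
#' @param info_dist function of `n` returning simulated imputation INFO
#'   scores in `[0,1]`.
#' @param posterior_low_frac fraction of tracts assigned a degraded posterior
#'   drawn uniformly in `[0.5, 0.9)`; all other tracts get posterior 1.0.
#' @param traits list of [trait_spec()] objects.
#' @param n_census_tracts number of census-tract clusters.
#' @param tract_intercept_sd s.d. of the tract-level random intercept feeding
#'   the nSES quintiles (and, per trait, the clustered noise term).
#' @param seed integer seed governing all stages (stage-specific seeds are
#'   derived from it; see [simulate_cohort()]).
#' @return object of class `sim_config` (a list).
#' @export
sim_config <- function(n_individuals = 500,
                       ancestries = c("PNS", "EUR", "EAS", "AFR"),
                       dirichlet_alpha = 5 * c(0.402, 0.296, 0.290, 0.012),
                       generations = 10,
                       map = constant_rate_map(c(`1` = 5e7, `2` = 5e7), 1000),
                       n_variants = 400,
                       fst = 0.1,
                       info_dist = function(n) stats::runif(n, 0.5, 1),
                       posterior_low_frac = 0,
                       traits = default_traits(),
                       n_census_tracts = 40,
                       tract_intercept_sd = 0.5,
                       seed = 1L) {
  stopifnot(length(dirichlet_alpha) == length(ancestries))
  if (any(dirichlet_alpha <= 0)) stop("dirichlet_alpha must be > 0", call. = FALSE)
  if (generations <= 0) stop("generations must be > 0", call. = FALSE)
  if (posterior_low_frac < 0 || posterior_low_frac > 1) {
    stop("posterior_low_frac must be in [0,1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Phenotype model for one simulated trait
#'
#' @param name trait column name.
#' @param type `"quantitative"` or `"binary"`.
#' @param intercept intercept of the linear predictor (quantitative only; the
#'   binary intercept is solved numerically from `prevalence`).
#' @param sigma residual s.d. (quantitative only).
#' @param prevalence target expected prevalence (binary only), in (0,1).
#' @param beta_ancestry named vector of per-unit global-ancestry effects.
#' @param beta_local effect per copy of local ancestry `local_ancestry_of` at
#'   (`causal_chrom`, `causal_pos`).
#' @param local_ancestry_of ancestry whose local dosage carries `beta_local`.
#' @param causal_chrom,causal_pos coordinates of the local causal locus.
#' @param beta_variant effect per ALT allele of the causal variant
#'   `causal_variant` (a variant id in the simulated dosage matrix).
#' @param causal_variant variant id carrying `beta_variant`.
#' @param beta_covariates named list of covariate effects; recognized names
#'   are `age`, `sexM`, `education`, `smoking` (per ordinal level
#'   never/former/current), `nses`, and `bmi` (value of the simulated `bmi`
#'   trait, allowing BMI-dependent disease models).
#' @param tract_sd s.d. of a census-tract-level intercept added to this
#'   trait's linear predictor.
#' @return object of class `trait_spec` (a list).
#' @export
trait_spec <- function(name, type = c("quantitative", "binary"),
                       intercept = 0, sigma = 1, prevalence = NULL,
                       beta_ancestry = NULL,
                       beta_local = 0, local_ancestry_of = "PNS",
                       causal_chrom = NULL, causal_pos = NULL,
                       beta_variant = 0, causal_variant = NULL,
                       beta_covariates = list(), tract_sd = 0) {
  type <- match.arg(type)
  if (type == "binary") {
    if (is.null(prevalence)) stop("binary trait needs a prevalence", call. = FALSE)
    if (prevalence <= 0 || prevalence >= 1) {
      stop("target prevalence must be in (0,1)", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "trait_spec")
}

#' Default simulated traits: raw-scale BMI and T2D status
#'
#' BMI is generated on its natural scale (kg/m^2, intercept 28, residual s.d.
#' 4) so the 32 kg/m^2 obesity cutoff is meaningful; its PNS effect of 0.59
#' trait-s.d. per unit ancestry matches the scale of reported global-ancestry
#' effects. T2D is binary with an expected prevalence of 0.171 and a
#' BMI-mediated component.
#'
#' @return list of [trait_spec()] objects.
#' @export
default_traits <- function() {
  list(
    trait_spec("bmi", "quantitative",
      intercept = 28, sigma = 4,
      beta_ancestry = c(PNS = 0.59 * 4, EAS = -0.64 * 4),
      beta_covariates = list(age = 0.02, sexM = -0.4, education = -0.3),
      tract_sd = 0
    ),
    trait_spec("t2d", "binary",
      prevalence = 0.171,
      beta_ancestry = c(PNS = 0.8, EAS = 0.7),
      beta_covariates = list(age = 0.03, sexM = 0.2, bmi = 0.08)
    )
  )
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate per-haplotype local ancestry tracts
#'
#' For each individual, global proportions `q` are drawn from
#' `Dirichlet(alpha)`; on each haplotype and chromosome, switch points are
#' placed as a Poisson process of rate `generations` per Morgan and each
#' tract's ancestry is drawn independently from `q` (the exchangeable
#' Markov-stationary pulse model). Adjacent same-ancestry segments are merged,
#' so tract lengths are approximately Exponential with mean
#' `1/(g (1 - sum q^2))` Morgans. A configured fraction of tracts receives a
#' degraded posterior drawn uniformly in `[0.5, 0.9)`; the rest get 1.0.
#'
#' The drawn proportions are attached as attribute `q_true` (a tibble) for
#' parameter-recovery tests.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` when given.
#' @return a [local_ancestry_set()].
#' @export
simulate_local_ancestry <- function(config, seed = config$seed) {
  set.seed(seed)
  map <- config$map
  K <- length(config$ancestries)
  lens <- map_chrom_lengths(map)
  if (any(lens <= 0)) stop("zero-length chromosome", call. = FALSE)
  chroms <- names(lens)
  glen_cm <- vapply(chroms, function(ch) bp_to_cm(map, ch, lens[[ch]]),
                    numeric(1))
  q <- .rdirichlet(config$n_individuals, config$dirichlet_alpha)
  colnames(q) <- config$ancestries
  ids <- sprintf("ind%04d", seq_len(config$n_individuals))
  rows <- vector("list", config$n_individuals * 2 * length(chroms))
  k <- 0L
  for (i in seq_len(config$n_individuals)) {
    for (h in 1:2) {
      for (ci in seq_along(chroms)) {
        G <- glen_cm[ci] / 100 # Morgans
        n_sw <- stats::rpois(1, config$generations * G)
        cuts_cm <- sort(stats::runif(n_sw, 0, glen_cm[ci]))
        anc_idx <- sample.int(K, n_sw + 1, replace = TRUE, prob = q[i, ])
        # merge adjacent equal-ancestry segments into canonical tracts
        keep <- c(TRUE, anc_idx[-1] != anc_idx[-length(anc_idx)])
        anc_idx <- anc_idx[keep]
        cuts_cm <- cuts_cm[keep[-1]]
        bnd_bp <- round(cm_to_bp(map, chroms[ci], cuts_cm))
        bnd_bp <- bnd_bp[bnd_bp >= 1 & bnd_bp < lens[[ci]]]
        bnd_bp <- unique(bnd_bp)
        # degenerate rounding can re-merge neighbours; re-run length encode
        n_tr <- length(bnd_bp) + 1
        anc_idx <- anc_idx[seq_len(n_tr)]
        spos <- c(1, bnd_bp + 1)
        epos <- c(bnd_bp, lens[[ci]])
        rl <- rle(anc_idx)
        ends <- cumsum(rl$lengths)
        starts <- c(1, ends[-length(ends)] + 1)
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          individual = ids[i], haplotype = h, chrom = chroms[ci],
          spos = spos[starts], epos = epos[ends],
          ancestry = config$ancestries[rl$values]
        )
      }
    }
  }
  tr <- dplyr::bind_rows(rows[seq_len(k)])
  tr$posterior <- 1.0
  if (config$posterior_low_frac > 0) {
    n_low <- round(config$posterior_low_frac * nrow(tr))
    j <- sample.int(nrow(tr), n_low)
    tr$posterior[j] <- stats::runif(n_low, 0.5, 0.9)
  }
  la <- local_ancestry_set(tr, map, ancestries = config$ancestries)
  attr(la, "q_true") <- tibble::as_tibble(cbind(
    tibble::tibble(id = ids), tibble::as_tibble(q)
  ))
  la
}

#' Draw ancestry-specific allele frequencies (Balding-Nichols model)
#'
#' Each variant gets an ancestral frequency uniform on `[0.05, 0.95]` and
#' per-ancestry frequencies from a `Beta` with the given differentiation
#' `fst`, the standard model for frequency divergence between populations.
#'
#' @param n_variants number of variants.
#' @param ancestries ancestry labels.
#' @param fst differentiation parameter in (0,1).
#' @return matrix `n_variants` x `K` of frequencies, ancestry labels as
#'   column names.
#' @export
sim_allele_freqs <- function(n_variants, ancestries, fst = 0.1) {
  p0 <- stats::runif(n_variants, 0.05, 0.95)
  a <- p0 * (1 - fst) / fst
  b <- (1 - p0) * (1 - fst) / fst
  f <- vapply(seq_along(ancestries), function(k) stats::rbeta(n_variants, a, b),
              numeric(n_variants))
  if (n_variants == 1) f <- matrix(f, nrow = 1)
  colnames(f) <- ancestries
  f
}

#' Simulate genotype dosages given local ancestry
#'
#' Each haplotype's allele at a variant is Bernoulli with the allele frequency
#' of that haplotype's local ancestry at the variant position; the dosage is
#' the sum over the two haplotypes. INFO scores are drawn from
#' `config$info_dist` so downstream selection-test matching has realistic
#' imputation-quality structure.
#'
#' @param la a [local_ancestry_set()].
#' @param freqs matrix variants x ancestries of allele frequencies (see
#'   [sim_allele_freqs()]); rownames are ignored, row order defines variants.
#' @param positions tibble with columns `chrom`, `pos` of the variant
#'   coordinates; defaults to a uniform subsample of the marker grid.
#' @param info numeric vector of INFO scores (recycled); defaults to draws
#'   from `info_dist`.
#' @param info_dist function of `n` returning INFO scores.
#' @param seed RNG seed.
#' @return a [dosage_matrix()].
#' @export
simulate_genotypes <- function(la, freqs, positions = NULL, info = NULL,
                               info_dist = function(n) stats::runif(n, 0.5, 1),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- la$map
  if (is.null(positions)) {
    idx <- round(seq(1, nrow(map), length.out = nrow(freqs)))
    positions <- tibble::tibble(chrom = map$chrom[idx], pos = map$pos[idx])
  }
  if (nrow(positions) != nrow(freqs)) {
    stop("one frequency row per variant required", call. = FALSE)
  }
  lens <- map_chrom_lengths(map)
  out_of_range <- !positions$chrom %in% names(lens) |
    positions$pos < 1 | positions$pos > lens[as.character(positions$chrom)]
  if (any(out_of_range)) {
    stop("variant outside map range at row ", which(out_of_range)[1],
         call. = FALSE)
  }
  n <- length(la$individuals)
  M <- nrow(freqs)
  hap_anc <- hap_ancestry_at(la, positions) # list of two n x M ancestry-code mats
  dosage <- matrix(0, n, M)
  for (h in 1:2) {
    anc <- hap_anc[[h]]
    f <- matrix(NA_real_, n, M)
    for (k in seq_along(la$ancestries)) {
      sel <- anc == k
      if (!any(sel)) next
      if (!la$ancestries[k] %in% colnames(freqs)) {
        stop("no allele frequency column for ancestry ", la$ancestries[k],
             call. = FALSE)
      }
      f[sel] <- freqs[, la$ancestries[k]][col(anc)[sel]]
    }
    dosage <- dosage + matrix(stats::rbinom(n * M, 1, f), n, M)
  }
  if (is.null(info)) info <- info_dist(M)
  variants <- tibble::tibble(
    chrom = as.character(positions$chrom), pos = positions$pos,
    id = sprintf("var%04d", seq_len(M)),
    ref = "A", alt = "T", info = rep_len(info, M)
  )
  rownames(dosage) <- la$individuals
  o <- order(variants$chrom, variants$pos)
  dosage_matrix(variants[o, ], dosage[, o, drop = FALSE])
}

# integer ancestry code of each haplotype at given positions:
# list(h1, h2) of n_individuals x n_positions matrices
hap_ancestry_at <- function(la, positions, what = c("ancestry", "posterior")) {
  what <- match.arg(what)
  tr <- la$tracts
  anc_code <- match(tr$ancestry, la$ancestries)
  ids <- la$individuals
  n <- length(ids)
  M <- nrow(positions)
  out <- list(matrix(NA_real_, n, M), matrix(NA_real_, n, M))
  key <- paste(tr$individual, tr$haplotype, tr$chrom, sep = "\r")
  grp <- split(seq_len(nrow(tr)), key)
  pos_by_chrom <- split(seq_len(M), as.character(positions$chrom))
  for (g in grp) {
    i <- match(tr$individual[g[1]], ids)
    h <- tr$haplotype[g[1]]
    ch <- tr$chrom[g[1]]
    cols <- pos_by_chrom[[ch]]
    if (is.null(cols)) next
    j <- findInterval(positions$pos[cols], tr$spos[g])
    if (any(j < 1)) stop("position before first tract", call. = FALSE)
    val <- if (what == "ancestry") anc_code[g][j] else tr$posterior[g][j]
    out[[h]][i, cols] <- val
  }
  out
}

#' Simulate phenotypes and covariates for a cohort
#'
#' Covariates are generated once per cohort: age ~ N(55, 8) (rounded), sex
#' M/F, ordinal education 1-4, smoking never/former/current, and a census
#' tract per individual whose tract-level random intercept (s.d.
#' `tract_intercept_sd`) is ranked into nSES quintiles at the tract level.
#' Each quantitative trait is `intercept + X beta + N(0, sigma)`; each binary
#' trait is Bernoulli through a logistic link whose intercept is solved
#' numerically so the expected prevalence equals the target.
#'
#' @param la a [local_ancestry_set()] (used for local causal dosages).
#' @param ga tibble of true or estimated global proportions (columns `id` +
#'   one per ancestry), e.g. `attr(la, "q_true")`.
#' @param dosages a [dosage_matrix()] or `NULL` (needed only for
#'   variant-driven traits).
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed + 2`); genotypes are
#'   untouched by a change of phenotype seed.
#' @return a [cohort_table()].
#' @export
simulate_phenotypes <- function(la, ga, dosages = NULL, config,
                                seed = config$seed + 2L) {
  set.seed(seed)
  n <- length(la$individuals)
  ids <- la$individuals
  stopifnot(all(ids %in% ga$id))
  q <- as.matrix(ga[match(ids, ga$id), config$ancestries])
  age <- round(stats::rnorm(n, 55, 8))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  education <- sample(1:4, n, replace = TRUE, prob = c(0.15, 0.3, 0.3, 0.25))
  smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
  n_ct <- config$n_census_tracts
  census_tract <- sprintf("ct%03d", sample.int(n_ct, n, replace = TRUE))
  u_ct <- stats::rnorm(n_ct, 0, config$tract_intercept_sd)
  names(u_ct) <- sprintf("ct%03d", seq_len(n_ct))
  nses_ct <- as.integer(cut(rank(u_ct, ties.method = "first"),
                            breaks = 5, labels = FALSE))
  names(nses_ct) <- names(u_ct)
  nses <- nses_ct[census_tract]
  u <- u_ct[census_tract]
  smoking_code <- match(smoking, c("never", "former", "current")) - 1
  out <- tibble::tibble(
    id = ids, age = age, sex = sex, education = education,
    smoking = smoking, nses = as.integer(nses), census_tract = census_tract
  )
  types <- character(0)
  for (sp in config$traits) {
    eta <- rep(0, n)
    if (!is.null(sp$beta_ancestry)) {
      for (a in names(sp$beta_ancestry)) eta <- eta + sp$beta_ancestry[[a]] * q[, a]
    }
    if (sp$beta_local != 0) {
      if (is.null(sp$causal_chrom)) stop("beta_local needs causal coordinates",
                                         call. = FALSE)
      d <- local_dosage_at(la, sp$local_ancestry_of,
        tibble::tibble(chrom = sp$causal_chrom, pos = sp$causal_pos),
        min_posterior = 0
      )
      eta <- eta + sp$beta_local * d[, 1]
    }
    if (sp$beta_variant != 0) {
      if (is.null(dosages)) stop("beta_variant needs a dosage matrix", call. = FALSE)
      j <- match(sp$causal_variant, dosages$variants$id)
      if (is.na(j)) stop("causal variant ", sp$causal_variant, " not found",
                         call. = FALSE)
      eta <- eta + sp$beta_variant * dosages$dosage[match(ids, dosages$individuals), j]
    }
    bc <- sp$beta_covariates
    if (!is.null(bc$age)) eta <- eta + bc$age * (age - mean(age))
    if (!is.null(bc$sexM)) eta <- eta + bc$sexM * (sex == "M")
    if (!is.null(bc$education)) eta <- eta + bc$education * (education - 2.5)
    if (!is.null(bc$smoking)) eta <- eta + bc$smoking * smoking_code
    if (!is.null(bc$nses)) eta <- eta + bc$nses * (nses - 3)
    if (!is.null(bc$bmi)) {
      if (!"bmi" %in% names(out)) stop("bmi-dependent trait requires bmi first",
                                       call. = FALSE)
      eta <- eta + bc$bmi * (out$bmi - mean(out$bmi))
    }
    if (sp$tract_sd > 0) eta <- eta + (sp$tract_sd / config$tract_intercept_sd) * u
    if (sp$type == "quantitative") {
      out[[sp$name]] <- sp$intercept + eta + stats::rnorm(n, 0, sp$sigma)
    } else {
      c0 <- stats::uniroot(
        function(c) mean(stats::plogis(c + eta)) - sp$prevalence,
        lower = -30, upper = 30, tol = 1e-10
      )$root
      out[[sp$name]] <- stats::rbinom(n, 1, stats::plogis(c0 + eta))
    }
    types[sp$name] <- sp$type
  }
  cohort_table(out, types)
}

#' Simulate a complete cohort: tracts, genotypes and phenotypes
#'
#' Stage seeds are derived from `config$seed` (`seed` for tracts, `seed + 1`
#' for genotypes, `seed + 2` for phenotypes), so re-running with the same
#' configuration is fully reproducible and changing only the phenotype seed
#' leaves the genotypes unchanged.
#'
#' @param config a [sim_config()].
#' @return list with elements `la` ([local_ancestry_set()]), `freqs`,
#'   `dosages` ([dosage_matrix()]), `ga_true` (tibble of drawn proportions)
#'   and `cohort` ([cohort_table()]).
#' @export
simulate_cohort <- function(config = sim_config()) {
  la <- simulate_local_ancestry(config, seed = config$seed)
  set.seed(config$seed + 1L)
  freqs <- sim_allele_freqs(config$n_variants, config$ancestries, config$fst)
  dosages <- simulate_genotypes(la, freqs, info_dist = config$info_dist)
  ga_true <- attr(la, "q_true")
  cohort <- simulate_phenotypes(la, ga_true, dosages, config,
                                seed = config$seed + 2L)
  list(la = la, freqs = freqs, dosages = dosages, ga_true = ga_true,
       cohort = cohort)
}
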