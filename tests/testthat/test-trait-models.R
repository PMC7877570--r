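# cohort with controllable education effect structure
edu_cohort <- function(n = 600, level_means = c(0, 0, 0, 0), seed = 1) {
  set.seed(seed)
  edu <- sample(1:4, n, replace = TRUE)
  d <- tibble::tibble(
    id = as.character(seq_len(n)),
    age = round(stats::rnorm(n, 55, 8)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    education = edu,
    noise_cov = stats::rnorm(n),
    y = level_means[edu] + stats::rnorm(n)
  )
  cohort_table(d, c(y = "quantitative"))
}

test_that("a non-associated candidate is excluded; age and sex always kept", {
  co <- edu_cohort()
  spec <- select_covariates(co, "y", candidates = c("education", "noise_cov"),
                           categorical = "education")
  expect_equal(spec$always, c("age", "sex"))
  expect_false("noise_cov" %in% names(spec$retained))
  expect_false("education" %in% names(spec$retained))
})

test_that("education collapses to binary when only the top level differs", {
  co <- edu_cohort(level_means = c(0, 0, 0, 1.2), seed = 2)
  spec <- select_covariates(co, "y", candidates = "education",
                           categorical = "education")
  g <- spec$retained$education$groups
  expect_equal(unname(g[c("1", "2", "3")]), c(0L, 0L, 0L))
  expect_equal(unname(g["4"]), 1L)
})

test_that("education collapses to ternary when the top two levels differ", {
  co <- edu_cohort(level_means = c(0, 0, 1, 2), seed = 3)
  spec <- select_covariates(co, "y", candidates = "education",
                           categorical = "education")
  g <- spec$retained$education$groups
  expect_equal(unname(g[c("1", "2")]), c(0L, 0L))
  expect_equal(length(unique(g)), 3)
  expect_true(g["3"] != g["4"])
})

test_that("a constant trait is rejected", {
  co <- edu_cohort()
  co$y <- 1
  expect_error(select_covariates(co, "y"), "constant")
})

test_that("the inverse-normal residual transform normalizes and preserves order", {
  co <- edu_cohort(level_means = c(0, 0.5, 1, 1.5), seed = 4)
  spec <- select_covariates(co, "y", candidates = "education",
                           categorical = "education")
  z <- transform_quantitative(co, spec)
  expect_lt(abs(mean(z, na.rm = TRUE)), 1e-10)
  expect_equal(stats::sd(z, na.rm = TRUE), 1, tolerance = 5e-3)
  # ranks equal ranks of residuals from an independently coded fit
  g <- spec$retained$education$groups
  d <- data.frame(y = co$y, age = co$age, sex = co$sex,
                  edu = factor(g[as.character(co$education)]))
  r <- stats::resid(stats::lm(y ~ age + sex + edu, data = d))
  expect_equal(rank(z), unname(rank(r)))
  # Blom formula on the residual ranks
  n <- length(r)
  expect_equal(sort(z),
               sort(unname(stats::qnorm((rank(r) - 3 / 8) / (n + 1 / 4)))))
})

test_that("exact linear dependence on ancestry is recovered exactly", {
  sim <- shared_sim()
  ga <- sim$ga_true
  y <- 5 * ga$PNS
  eff <- suppressWarnings( # lm flags the intentionally perfect fit
    fit_global_ancestry_model(y, ga, trait_type = "quantitative")
  )
  expect_equal(eff$beta[eff$ancestry == "PNS"], 5, tolerance = 1e-8)
  expect_lt(eff$p[eff$ancestry == "PNS"], 1e-100)
  expect_equal(attr(eff, "baseline"), "EUR")
  expect_equal(nrow(eff), 3) # K - 1 coefficients
  expect_error(fit_global_ancestry_model(y, ga, trait_type = "quantitative",
                                         baseline = NULL), "baseline")
})

test_that("a simulated global PNS effect of 0.59 s.d. is recovered", {
  hits <- 0
  for (s in 1:10) {
    cfg <- sim_config(
      n_individuals = 350, seed = 100 + s,
      map = constant_rate_map(c(`1` = 5e7), 100),
      traits = list(trait_spec("y", "quantitative",
                               beta_ancestry = c(PNS = 0.59), sigma = 1))
    )
    la <- simulate_local_ancestry(cfg)
    ga <- attr(la, "q_true")
    co <- simulate_phenotypes(la, ga, config = cfg)
    eff <- fit_global_ancestry_model(co$y, ga, trait_type = "quantitative")
    b <- eff[eff$ancestry == "PNS", ]
    if (abs(b$beta - 0.59) <= 1.96 * b$se) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("per-10%-ancestry transformations are exact and monotone", {
  expect_equal(per_10pct_effect(0, "quantitative")$per10_sd, 0)
  expect_equal(per_10pct_effect(0, "binary")$or_per10, 1)
  expect_equal(per_10pct_effect(0, "binary")$pct_odds_per10, 0)
  b <- seq(-2, 2, by = 0.25)
  q <- vapply(b, function(x) per_10pct_effect(x, "quantitative")$per10_sd,
              numeric(1))
  o <- vapply(b, function(x) per_10pct_effect(x, "binary")$or_per10,
              numeric(1))
  expect_true(all(diff(q) > 0))
  expect_true(all(diff(o) > 0))
})

test_that("the census-tract mixed model degenerates to fixed effects", {
  cfg <- sim_config(
    n_individuals = 500, seed = 51, tract_intercept_sd = 0.5,
    map = constant_rate_map(c(`1` = 5e7), 80),
    traits = list(trait_spec("y", "quantitative",
                             beta_ancestry = c(PNS = 0.6), sigma = 1,
                             tract_sd = 0)) # no true between-tract variance
  )
  la <- simulate_local_ancestry(cfg)
  ga <- attr(la, "q_true")
  co <- simulate_phenotypes(la, ga, config = cfg)
  mixed <- suppressMessages(fit_nses_mixed_model(
    co$y, ga, cohort = co, trait_type = "quantitative"
  ))
  d <- as.data.frame(ga[, c("PNS", "EAS", "AFR")])
  d$y <- co$y
  d$nses <- co$nses
  fixed <- stats::lm(y ~ PNS + EAS + AFR + nses, data = d)
  expect_equal(mixed$beta, unname(stats::coef(fixed)[c("PNS", "EAS", "AFR")]),
               tolerance = 1e-3)
  # nSES independent of ancestry: ancestry beta close to the nSES-free model
  plain <- fit_global_ancestry_model(co$y, ga, trait_type = "quantitative")
  expect_equal(mixed$beta, plain$beta, tolerance = 0.05)
})

test_that("single-cluster input falls back to fixed effects with a warning", {
  sim <- shared_sim()
  ga <- sim$ga_true
  y <- stats::rnorm(nrow(ga))
  expect_warning(
    fit_nses_mixed_model(y, ga, cohort = sim$cohort,
                         trait_type = "quantitative",
                         nses = rep(3L, nrow(ga)),
                         cluster = rep("ct1", nrow(ga))),
    "single cluster"
  )
})

test_that("pooled interaction fit reproduces per-stratum coefficients exactly", {
  set.seed(60)
  sim <- shared_sim()
  ga <- sim$ga_true
  s <- stats::rbinom(nrow(ga), 1, 0.5)
  y <- 0.8 * ga$PNS * (s == 0) + 0.1 * ga$PNS * (s == 1) + stats::rnorm(nrow(ga))
  res <- stratified_and_interaction(y, ga, s, trait_type = "quantitative")
  b0 <- res$strata[["0"]]$beta
  b1 <- res$strata[["1"]]$beta
  cf <- stats::coef(res$fit)
  it <- res$interaction
  expect_equal(it$term, c("PNS", "EAS", "AFR"))
  expect_equal(unname(cf[c("PNS", "EAS", "AFR")]), b0, tolerance = 1e-8)
  expect_equal(unname(cf[c("PNS", "EAS", "AFR")]) + it$beta, b1,
               tolerance = 1e-8)
  expect_error(stratified_and_interaction(y, ga, rep(1, nrow(ga))),
               "two non-empty levels")
})

test_that("a designed ancestry-by-status interaction is detected", {
  # strong effect in controls, none in cases, as in BMI-by-T2D stratification
  hits <- 0
  for (rep in 1:10) {
    set.seed(70 + rep)
    n <- 800
    pns <- stats::runif(n, 0, 0.8)
    eas <- stats::runif(n) * (1 - pns) * 0.8
    afr <- stats::runif(n) * (1 - pns - eas) * 0.1
    ga <- tibble::tibble(id = as.character(seq_len(n)), PNS = pns, EAS = eas,
                         AFR = afr, EUR = 1 - pns - eas - afr)
    s <- stats::rbinom(n, 1, 0.5)
    y <- 0.87 * ga$PNS * (s == 0) + stats::rnorm(n, 0, 0.5)
    res <- stratified_and_interaction(y, ga, s, trait_type = "quantitative")
    i <- res$interaction[res$interaction$term == "PNS", ]
    if (i$beta < 0 && i$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("obesity labels use the 32 kg/m^2 cutoff", {
  sim <- shared_sim()
  ob <- label_obesity(sim$cohort$bmi)
  expect_equal(ob, as.integer(sim$cohort$bmi >= 32))
  expect_true(any(ob == 1) && any(ob == 0))
  expect_true(is.na(label_obesity(NA_real_)))
})

test_that("the 14-trait Bonferroni reporting flag uses 0.05/14", {
  expect_true(significant_14traits(0.003))
  expect_false(significant_14traits(0.004))
})
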