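Package: admixscan
Title: Ancestry Association and Admixture Mapping for Recently Admixed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for studying the effect of genetic ancestry
    on complex traits in recently admixed populations. Computes per-individual
    global ancestry proportions from posterior-filtered local-ancestry tracts,
    tests global ancestry against quantitative and binary traits with a
    univariate covariate-retention heuristic and rank-based inverse-normal
    residuals, fits census-tract random-intercept models for neighborhood
    socioeconomic adjustment, performs genome-wide admixture mapping of local
    ancestry dosage with a permutation-calibrated significance threshold,
    defines signal and broad candidate regions, runs conditional and
    EMMAX-style mixed-model single-variant association with regional
    permutation significance, computes the nSL haplotype selection statistic
    with a frequency- and imputation-quality-matched empirical null, and
    provides an analytic one-stage case-control power calculation. A
    synthetic-cohort simulator (Dirichlet global proportions, Poisson
    ancestry-switch tracts, ancestry-specific allele frequencies, clustered
    covariates) makes every stage testable without controlled-access data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    lme4,
    readr,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
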