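# admixscan

Ancestry-association and admixture-mapping analysis for recently admixed
cohorts, written for statistical geneticists studying populations — such as
Native Hawaiians and other Polynesian-ancestry communities — where global
genetic ancestry, local ancestry tracts, and population-specific variants all
carry signal about cardiometabolic disease risk.

## What it computes

With `q` the vector of per-individual global ancestry proportions
(PNS/EUR/EAS/AFR by default) obtained by summing posterior-filtered
local-ancestry tract lengths, the package fits, per trait `y`:

* **Global ancestry association** — `INT(resid(y ~ covariates)) ~ q_PNS +
  q_EAS + q_AFR` (EUR baseline) for quantitative traits, with covariates
  chosen by a univariate retention heuristic and collapsed categorical
  codings; joint logistic models for binary traits. Effects are reported per
  10% ancestry: `0.1·β` (s.d.) or `exp(0.1·β)` (odds ratio).
* **Admixture mapping** — at every marker `m`, `y ~ d_PNS(m) + q_EUR + q_EAS
  + q_AFR`, where `d_PNS(m) ∈ {0,1,2}` is the local PNS ancestry dosage;
  genome-wide significance is the lower 5% quantile of the minimum P over
  permuted standard-normal phenotypes, and significant runs of markers are
  grown into signal and broad candidate regions.
* **Fine-mapping** — EMMAX two-step linear mixed model in a candidate
  region: `V = σ²_g K + σ²_e I` with a VanRaden GRM `K`, REML for
  `λ = σ²_g/σ²_e` under the null, per-variant GLS Wald tests, and a regional
  permutation threshold.
* **Selection** — the nSL statistic (log ratio of mean pairwise
  haplotype-sharing lengths between derived- and ancestral-allele carriers),
  standardized in derived-allele-frequency bins, with empirical P-values
  against a DAF- and INFO-matched null set.
* **Replication power** — the one-stage GAS/CaTS case-control power of the
  allelic test under Hardy–Weinberg genotypes and multiplicative per-allele
  risk.

A synthetic-cohort module (Dirichlet global proportions, Poisson
ancestry-switch tracts, Balding–Nichols allele frequencies, census-tract
clustered covariates) generates data with exactly the structure these models
assume, so the whole pipeline is testable without controlled-access cohort
data. See `vignettes/ancestry-association-methods.Rmd` for the models,
assumptions and design choices.

## Worked example

```r
library(admixscan)

cfg <- sim_config(seed = 7)            # 500 individuals, 2 x 50 Mb, K = 4
sim <- simulate_cohort(cfg)

ga  <- compute_global_ancestry(sim$la, min_posterior = 0.9)
spec <- select_covariates(sim$cohort, "bmi")
y   <- transform_quantitative(sim$cohort, spec)
fit_global_ancestry_model(y, ga, trait_type = "quantitative")
#>   ancestry   beta    se       p
#> 1 PNS       0.291 0.214 0.175
#> 2 EAS      -0.627 0.232 0.00711
#> 3 AFR      -0.380 0.792 0.631
```

Each row is the effect of one ancestry component, in trait standard
deviations per unit ancestry proportion relative to the European baseline:
in this simulated cohort a full swap from EUR to EAS ancestry predicts a
0.63 s.d. *lower* BMI (P = 0.007), while the PNS effect (simulated at +0.59
s.d. before covariate noise and ancestry correlations) is attenuated and not
significant at n = 500. `per_10pct_effect(0.291, "quantitative")` rescales
this to 0.029 s.d. per 10% ancestry.

```r
scan <- admixture_scan(y, sim$la, ga)                     # 2,000 markers
th   <- permutation_threshold(sim$la, ga, n_perm = 500, seed = 8)
th
#> <threshold_estimate> 0.000339 (lower 5% quantile of 500 permutation minima)
min(scan$p, na.rm = TRUE)
#> [1] 0.00564
define_regions(scan, th)                                  # empty: null trait
```

The genome-wide threshold (3.4e-4 on this small simulated genome; the
denser the map and the longer the genome, the smaller it gets) exceeds the
best scan P-value, so no region is declared — as expected for a trait
simulated without a local driver.

```r
gas_power(power_params(n_cases = 475, n_controls = 2377, prevalence = 0.171,
                       risk_allele_freq = 0.087, grr = 1.096))
#> [1] 0.1431283
```

That is the power (14.3%) of a 475-case / 2,377-control replication study to
detect, at nominal α = 0.05, a per-allele relative risk of 1.096 for an
allele at 8.7% frequency in a disease with 17.1% prevalence — small enough
that a failure to replicate is uninformative.

Every stage is also reachable from a shell via the installed `admixscan`
script (`exec/admixscan`), e.g.
`admixscan simulate --seed 1 --out-dir sim/` then
`admixscan admixmap --tracts sim/tracts.tsv --map sim/map.tsv
--phenotypes sim/phenotypes.csv --ancestry ga.tsv --trait bmi --out scan.tsv`.

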