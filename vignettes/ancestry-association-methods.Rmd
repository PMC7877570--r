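---
title: "Models and methods behind admixscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind admixscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixscan)
```

# The scientific problem

Recently admixed populations — here modelled on a four-way Polynesian
(PNS) / European (EUR) / East Asian (EAS) / African (AFR) admixture — carry
information about trait-associated variation at two scales. Globally, an
individual's genome-wide ancestry proportions may correlate with disease risk
through both genetic and correlated environmental pathways. Locally, a causal
allele whose frequency differs between ancestral populations drags the
surrounding ancestry tract into association with the trait, which is what
admixture mapping detects. `admixscan` implements this two-scale analysis
end to end: global-ancestry trait models with a covariate-selection
heuristic, a genome-wide local-ancestry scan with permutation-calibrated
significance, region definition and conditional analysis, mixed-model
single-variant fine-mapping, a haplotype-based selection statistic with a
matched empirical null, and an analytic replication power calculation.

Because the cohorts this methodology targets are controlled-access, the
package ships a synthetic-cohort generator with the statistical structure the
analysis assumes, so every stage is exercised by tests on data whose truth is
known.

# Global ancestry from local tracts

Global proportions are computed by summing the genetic length (cM) of
local-ancestry tracts per ancestry over both haplotypes, after excluding
tracts with posterior probability below 0.9, then renormalizing to sum to 1.
Two choices here were genuinely open:

* **Unit of length.** We measure tracts in genetic distance, falling back to
  an equivalent basepair tally under a constant-rate map. Genetic length
  matches the semantics of ancestry proportions and is invariant to marker
  density.
* **Filter granularity and renormalization.** The 0.9 posterior filter is
  applied at the tract level (a whole tract is kept or dropped), and
  proportions are renormalized over the retained length. Renormalization is
  required by the downstream regressions, which use K−1 proportions against a
  baseline and assume they lie on the simplex. An individual whose entire
  genome is filtered out is reported as missing rather than zero.

# Trait models

For a quantitative trait, candidate covariates are screened one at a time;
age and sex are always retained, and any candidate with a nominally
significant univariate association (P < 0.05; the cutoff is a package
default, exposed as `alpha`) is kept. Retained categorical covariates are
collapsed: levels whose level-vs-reference contrast is not significant are
merged into the reference, typically reducing education to a binary or
ternary coding. The trait is then residualized on the retained covariates
jointly and the residuals are mapped through the rank-based inverse-normal
transform with the Blom offset, `qnorm((rank − 3/8)/(n + 1/4))`. We chose the
inverse-normal transform over plain z-scoring because the per-trait model
legends this pipeline follows specify inverse-normalized residuals; plain
standardization is recoverable by skipping the transform. Note the Blom
scores have s.d. slightly below 1 (≈0.9975 at n = 500); tests assert
normalization at that accuracy, not at machine precision.

The transformed trait is regressed jointly on the PNS, EAS and AFR
proportions with EUR as baseline; binary traits keep their covariates inside
a joint logistic model instead of being residualized (residuals of a 0/1
outcome are not a binomial response). All coefficient P-values are Wald
tests. Effects are reported per 10% ancestry: `0.1·β` in trait s.d. for
quantitative traits, `exp(0.1·β)` as an odds ratio for binary ones.

Neighborhood socioeconomic status is assigned at the census-tract level, so
individuals in a tract share the value; the nSES model therefore includes a
census-tract random intercept (lme4), with a fixed-effects fallback when only
one cluster is present. Stratified analyses refit the model per stratum, and
the pooled interaction model adds ancestry-by-stratum products; for linear
models the two parameterizations are algebraically equivalent, which the test
suite exploits as an oracle.

# Admixture mapping and its significance threshold

At each marker the trait is regressed on the local PNS dosage (0–2) with the
EUR/EAS/AFR global proportions as covariates. The quantitative-trait scan is
a vectorized least-squares sweep (Frisch–Waugh–Lovell residualization against
the shared covariates), identical to per-marker multiple regression to
floating-point accuracy; binary traits use per-marker logistic fits with the
individual-level covariates included.

Genome-wide significance is calibrated by permutation: 1,000 genome scans of
standard-normal phenotypes drawn independently of all data, keeping each
scan's minimum P-value; the threshold is the lower 5% quantile of those
minima. This is family-wise error control given the realized correlation of
local ancestry — the procedure is sometimes described with false-discovery
vocabulary, but what the minimum-P quantile controls is the family-wise rate,
and the test suite verifies exactly that (the fraction of fresh null scans
whose minimum P crosses the threshold is ~5%). Binary traits are calibrated
with the same normal-phenotype linear scans rather than per-trait case
shuffling, matching the single calibrated threshold used per scan family.
With near-independent markers the threshold approaches the Šidák bound
`1 − (1 − 0.05)^(1/M)`, and stronger local-ancestry correlation can only
loosen it; both behaviours are asserted in tests. The conventional published
constant 2.2e-5 is available as a CLI preset but is always recomputable.

Signal regions are maximal runs of markers strictly below the genome-wide
threshold (ties at the threshold do not qualify); boundaries sit at marker
positions, with no interpolation. The broad region extends the signal region
through suggestive markers (−log10 P > 4) within 5 Mb, merging qualifying
segments up to 5 Mb apart — the flank rule is primary and the merge rule is
applied on top of it. Conditional scans append user-supplied variant dosages
to the covariates, dropping columns that are collinear with what is already
in the model.

# Mixed-model fine-mapping

Single-variant association inside a candidate region uses the two-step EMMAX
scheme: a VanRaden genomic relationship matrix (frequency-standardized
cross-product, ridge 1e-6 on the diagonal for PSD safety), top-10 GRM
principal components as structure covariates, REML estimation of the variance
ratio λ = σ²g/σ²e on the GRM eigenbasis under the null, and per-variant
generalized least squares with that covariance held fixed. We use a plain
GRM + PCA rather than ancestry-robust kinship estimators: those guard against
admixture-induced bias in kinship at biobank scale, which the desk-scale
synthetic cohorts here do not exhibit; the module boundary accepts any
kinship matrix if a robust one is available. Step 2 is implemented as
ordinary least squares in the whitened space with a Wald t-test — the EMMAX
software's own formulation — so with an identity kinship the result collapses
exactly to OLS. Binary traits are analyzed as 0/1 outcomes on the linear
scale, standard EMMAX practice that trades link-scale interpretability for a
correctly calibrated test under relatedness. The outcome is standardized
internally (and effect sizes mapped back), making results exactly invariant
to affine rescaling of the trait. Variants are filtered at INFO ≥ 0.4 and
MAF ≥ 1% before testing. Regional significance comes from 1,000 residual
permutations (covariate-adjusted residuals permuted and re-added to the
fitted values), rerunning the mixed model each time and taking the lower 5%
quantile of the regional minimum P.

# Selection statistic

`compute_nsl` contrasts mean pairwise haplotype-sharing lengths — counted in
markers, capped at 100 markers per direction, the common scan default —
between derived- and ancestral-allele carriers at a focal site. The default
sign convention is `log(mean derived / mean ancestral)`, so positive values
mean the derived allele rides the longer haplotypes; the convention is an
explicit argument because both orientations appear in the literature. Raw
values are standardized within derived-allele-frequency bins (50 equal-width
bins, bins under 20 values merged leftward). Empirical significance compares
the focal variant with all variants inside a DAF and INFO matching window
(defaults 0.23–0.25 and 0.77–0.97), using the `(r+1)/(n+1)` estimator so the
P-value is never zero. Both the standardized and unstandardized statistics
are reported, since a one-sided empirical P can be taken on either.

# Power calculation

`gas_power` is the one-stage case-control computation of the CaTS/GAS family:
Hardy–Weinberg genotype frequencies, multiplicative per-allele risk scaled so
the population prevalence matches, expected risk-allele frequencies in cases
and in *unaffected* (not population) controls, and the two-sided
two-proportion allele-count test evaluated by the normal approximation with
the variance under the alternative (equivalently, the 1-df chi-square
noncentrality form). We verified numerically that a variant using the
pooled-null standard error for the rejection threshold gives a visibly
different (higher) value and does not match the published calculator's
behaviour, so the noncentrality form is used; a 20,000-replicate Monte-Carlo
oracle in the test suite bounds the approximation error. At a unit relative
risk the power equals α exactly.

# The synthetic-cohort generator

The generator is the package's stand-in for controlled-access cohort data; it
emulates the features the analysis relies on and nothing more.

* **Global ancestry**: Dirichlet with mean ≈ (0.402, 0.296, 0.290, 0.012)
  for PNS/EUR/EAS/AFR — the ancestry composition profile of the target
  population — and total concentration 5, giving the broad spread of
  individual proportions seen in recently admixed cohorts.
* **Local ancestry**: per haplotype, switch points as a Poisson process of
  rate g per Morgan with tract ancestries i.i.d. from the individual's
  proportions (the exchangeable pulse model that underlies admixture-mapping
  threshold theory), g = 10 by default, consistent with admixture beginning
  roughly two to three centuries ago. Adjacent same-ancestry segments are
  merged, so realized tract boundaries thin the Poisson rate by
  `1 − Σ q²`. A configurable fraction of tracts receives a degraded
  posterior uniform on [0.5, 0.9), placed uniformly at random — enough to
  exercise the 0.9 filter without modelling caller error structure.
* **Genotypes**: Balding–Nichols ancestry-specific frequencies (Fst 0.1 by
  default), haplotype alleles Bernoulli given the local ancestry; INFO
  scores from a configurable distribution so imputation-quality matching has
  structure to work with.
* **Phenotypes**: linear predictors over global ancestry, an optional local
  causal locus (ancestry dosage or variant dosage), and SES-like covariates;
  census tracts carry a random intercept whose tract-level ranking defines
  the nSES quintiles. Binary traits solve the logistic intercept numerically
  to hit a target prevalence (0.171 for the default T2D-like trait). BMI is
  generated on its natural scale so the 32 kg/m² obesity cutoff for
  Polynesian-ancestry cohorts is meaningful.
* **Map**: constant 1 cM/Mb over 2 chromosomes × 50 Mb with 1,000 markers
  each by default; local-ancestry inference has been shown to be robust to
  constant-rate maps, and the desk-scale tests do not depend on hotspot
  structure.

What the generator does *not* emulate: linkage disequilibrium beyond
ancestry-induced correlation, coalescent haplotype genealogies, selection,
genotyping error, or realistic missingness. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated model,
not robustness to everything real data can do.

Stage seeds are derived from one base seed (tracts, genotypes and phenotypes
offset by 0/1/2), so cohorts are bit-reproducible and changing only the
phenotype seed leaves genotypes untouched.

# Numerical and interface choices

* Coordinates are 1-based closed intervals, matching the inclusive start–stop
  convention of region tables.
* Tract files are a tract-per-row TSV (individual, haplotype, chm, spos,
  epos, ancestry, posterior) with a `#codes:` header naming the ancestry
  codes. A window-per-row wide layout was considered and rejected: per-tract
  posteriors cannot be represented in it without parallel column blocks, and
  the long layout keeps the write/read pair a lossless round trip, which the
  IO tests require.
* Marker grids between local-ancestry calls and dosage files are aligned by
  exact (chromosome, bp) match; no interpolation across files.
* Missing data are handled by complete-case analysis per trait, with the
  retained-covariate set defining completeness.
* The permutation-threshold quantile is the lower type-1 (order-statistic)
  empirical quantile; collinear or constant markers yield NA rows with the
  scan otherwise proceeding.
* Problem sizes in the test suite (cohorts of 120–600, genomes of 1–35
  Morgans, 100-replicate recovery loops, 1,000-permutation thresholds) were
  chosen as the smallest designs at which the checked properties have
  stable power; the same code paths scale to cohort-sized inputs.

# Known limitations

* The logistic admixture scan refits per marker and is correspondingly
  slower than the vectorized linear scan.
* The binary-trait mixed model is linear on 0/1 outcomes; odds ratios
  reported from it are first-order approximations (`exp(beta)` on the linear
  scale), as in the EMMAX tradition.
* `nSL` here uses marker counts, not genetic distance, and a fixed
  100-marker cap; statistics near panel edges are shrunk by the cap, which
  the DAF-binned standardization absorbs only in expectation.
* The covariate-retention heuristic inherits the instability of any
  stepwise screen near the retention threshold; `covariate_spec` objects are
  explicit so a fixed model can be supplied instead.
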