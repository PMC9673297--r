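---
title: "Methods: multi-trait mixed-model GWAS for low-coverage sequencing cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-trait mixed-model GWAS for low-coverage sequencing cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`lcsgwas` implements the statistical stages of a genetic-architecture
analysis for cohorts genotyped by low-coverage whole-genome sequencing
(LCS) followed by imputation: imputation-accuracy evaluation, variant QC,
the VanRaden genomic relationship matrix (GRM), multi-trait REML variance
components and heritability, multivariate and conditional Wald GWAS,
simulation-based QTL confidence intervals, QTL heritability, and
sliding-window population-genetic statistics. Read alignment, variant
calling and the imputation engines themselves are out of scope; the
package starts from VCF genotypes/dosages and phenotype tables.

# The model

For `t` traits (one trait at `t` time points) measured on `n` individuals,
the stacked phenotype vector follows

    y = (I_t (x) X) b + u + e,
    u ~ N(0, Sigma_u (x) K),      e ~ N(0, Sigma_e (x) I_n),

where `X` holds the fixed effects (intercept, sex, housing unit dummies),
`K` is the VanRaden GRM

    K = W W' / sum_j 2 p_j (1 - p_j),   w_ij = m_ij - 2 p_j,

with `m_ij` the 0/1/2 genotype and `p_j` the per-SNP centering frequency,
and `Sigma_u`, `Sigma_e` are `t x t` genetic and residual trait covariance
matrices. Per-trait narrow-sense heritability is
`h2_i = Sigma_u[i,i] / (Sigma_u[i,i] + Sigma_e[i,i])`; genetic correlations
come from the off-diagonals of `Sigma_u`.

The centering frequency deserves a note: the standard VanRaden construction
centers by the alternate-allele frequency, while some descriptions call
`p_j` "the MAF". The two differ exactly at sites where the alternate allele
is the major one. Both conventions are implemented
(`vanraden_grm(..., freq_convention = c("alt", "maf"))`); `"alt"` is the
default and every GRM records the convention it used. The denominator is
identical under both.

Missing data contracts: genotype containers use `NA` as the missing
sentinel. The GRM mean-imputes missing calls per SNP (so they contribute
exactly zero to `W`); the model frame is strictly complete-case (dropped
individuals are counted); association scans mean-impute missing genotypes
per SNP.

# REML by double diagonalization

`fit_mtlmm()` maximizes the restricted likelihood over PSD
`(Sigma_u, Sigma_e)`. Two rotations make every evaluation cheap:

1. `K = U L U'` is eigendecomposed once; rotating phenotypes and design by
   `U'` makes individuals independent with per-individual covariance
   `lambda_i Sigma_u + Sigma_e`.
2. At each parameter value, the trait-space transformation `T` with
   `T' Sigma_u T = diag(d)` and `T' Sigma_e T = I` (Cholesky of `Sigma_e`
   plus one symmetric eigendecomposition) fully diagonalizes the problem:
   the likelihood becomes `t` independent weighted regressions with
   per-observation weights `1 / (lambda_i d_k + 1)`.

The optimizer is average-information (AI) REML with step-halving,
warm-started by two EM-REML iterations. An AI proposal is accepted only if
the (eigenvalue-clipped) update does not decrease the restricted
likelihood; otherwise the EM update is taken, which cannot decrease it.
Numerical choices:

* **PSD projection** — after each AI step both matrices are clipped to the
  PSD cone by flooring eigenvalues at `1e-6 * trace / t`. `Sigma_e`
  additionally keeps a floor of `1e-6` times the mean phenotypic variance:
  a residual covariance collapsing to numerical zero (possible at very
  small `n`) would otherwise create weight ratios of 1e8 and ruin the
  conditioning of subsequent scans.
* **Starting values** — `Sigma_u = Sigma_e = cov(Y) / 2`.
* **Convergence** — absolute restricted log-likelihood change below `tol`
  (default `1e-8`) *and* maximum parameter change below `1e-6` relative to
  the largest current parameter. The relative test is on the overall
  parameter scale rather than per entry, because near-boundary entries of
  order 1e-8 would otherwise oscillate forever without affecting the fit.
* **Identifiability** — if all GRM eigenvalues are equal (`K` proportional
  to `I`), only `Sigma_u + Sigma_e` is identified; the fit warns and flags
  itself.

The restricted log-likelihood includes all constant terms, so
`mtlmm_loglik()` is directly comparable with a dense-matrix evaluation of
the REML objective; the test suite holds the rotated computation to a
brute-force `(tn x tn)` oracle at `1e-8`.

# Association testing

`multivariate_gwas()` adds one SNP at a time as `t` fixed effects and
tests `W = alpha' var(alpha)^{-1} alpha ~ chi2(t)`. Variance components are
held fixed at the null REML estimates for every SNP — the standard
"population parameters previously determined" approximation; per-SNP REML
refits would cost a full fit per variant and give nearly identical tests at
these sample sizes. Because the double rotation diagonalizes everything,
a whole-genome scan is a handful of matrix products; effects and their
covariances are rotated back to the original trait scale for reporting.
SNPs with MAF below 1e-6 among tested samples, or with a singular effect
covariance, are skipped and counted.

`conditional_gwas()` appends the lead SNP's genotype as `t` extra fixed
covariates and re-tests every other SNP, skipping those essentially
collinear with the lead (|r| > 0.9999). The multiple-testing threshold is
`0.05 / N` with `N` the number of SNPs retained by LD pruning
(`ld_prune()`, a deterministic re-statement of PLINK-style
`--indep-pairwise` counted in SNPs; the removal rule — drop the
smaller-MAF member, ties to the larger position — is documented as
approximating, not bit-matching, the reference tool, whose tie handling is
unpublished). `cluster_qtl()` merges significant SNPs within 1 Mb (a
documented default; the clustering rule behind published QTL counts is
typically unstated) into QTL with min-p lead SNPs.

# Drop-log(P) confidence intervals

`drop_logp_ci()` extends the drop-log(P) interval to the multivariate
model. The candidate region is the QTL bounds padded by 1 Mb (the extent
of "the candidate QTL region" is a package choice; published analyses
leave it unstated). The lead SNP's estimated effect vector is removed from
the phenotypes; each simulation assigns that effect to a randomly chosen
region SNP (without replacement while the region has at least `n_sims`
SNPs, else with), rescans the region with variance components fixed (fixed
effects are refit implicitly by the projection), and records the drop in
`-log10 p` between the scan's best SNP and the simulated causal SNP. The
95th percentile `D` of the drops defines the interval: all region SNPs
whose observed `-log10 p` is within `D` of the observed lead, reported as
`[min pos, max pos]` with width `end - start + 1`. Tail probabilities are
computed on the log scale, so the procedure survives p-value underflow at
very strong QTL. Everything is reproducible bit-for-bit under the `seed`
argument.

`qtl_heritability()` refits the REML model with the lead SNP as a fixed
covariate and reports the per-trait drop in heritability, clamped at zero
with a warning when sampling noise makes it negative (how published
analyses handled negative drops is unstated). Two properties of this
estimator matter for interpretation: the drop can recover the injected
variance fraction only to the extent that the causal SNP's effect is
absorbed into the genetic variance of the unadjusted fit — which requires
the SNP to be well tagged by the markers building the GRM — and even under
perfect absorption its estimand is `frac * (1 - h2_adj)` rather than
`frac` itself, so it is attenuated under strong polygenic backgrounds. The
recovery test therefore uses a dense, high-LD map and a weak (h2 = 0.10)
background, where the estimand is within a couple of points of the nominal
fraction; under a 0.3-0.4 background the same estimator would structurally
report ~70% of the injected fraction.

# Imputation accuracy

Truth and test sites are matched on the exact key (chrom, pos, ref, alt) —
swapped alleles at the same position do not match. Genotype concordance
(GC) is the per-site fraction of hard-called imputed genotypes equal to
the truth call, averaged over sites; hard calls take the GP-argmax (ties
to the heterozygote) or, lacking GP, the dosage rounded half-up. Genotype
accuracy (GA) is the per-site Pearson correlation between imputed dosage
and truth code across samples (at least 3 paired observations;
zero-variance sites are skipped and counted); a pooled all-cells
correlation is also reported, since published summaries rarely state which
weighting they use. MAF bins of width 0.05 use the truth-set MAF with
half-open bins, the last closed at 0.5.

# Windowed population genetics

Windows are anchored at position 1 of each chromosome, 50 kb wide with
10 kb steps by default; trailing partial windows are kept and flagged.
Per-site diversity is the unbiased `2ab / (N(N-1))` on allele counts;
window values are per-bp (divided by the nominal window length).
Between-population differentiation is Weir & Cockerham's (1984) estimator
from genotype counts, with window values as ratio-of-sums (the weighted
estimator used by the common VCF tools); negative values are legitimate
and kept. Outlier windows at a configurable top quantile (different
analyses use top 1% or top 5%, so it is a parameter) are merged when
overlapping or bookended; an optional z-transform standardizes the
statistic first.

# The synthetic cohort generator

`sim_config()` / `simulate_genotypes()` / `simulate_phenotypes()` /
`simulate_lcs_dosages()` emulate the statistical structure the pipeline
assumes, defaulting to the study conditions the package targets: ~600
diploid individuals in one cohort, two sexes and 5 housing units with
modest fixed effects, traits at 3 time points with unit phenotypic
variance, `h2 = 0.3` and genetic correlation 0.5, SNPs with founder MAF
uniform on [0.05, 0.5], and QTL injected at a few percent of phenotypic
variance. Genotypes come from Markov copying over a founder haplotype
pool: 20 founder haplotypes and a per-SNP switch probability of 0.01,
chosen to mimic a closed, intensely selected breeding population with high
relatedness and very slow LD decay (the regime in which LCS imputation and
GRM-based REML are most informative). QTL effect sizes are solved from the
requested variance fraction via `2p(1-p) beta^2 = frac * V_ph`, where
`V_ph` scales `Sigma_u + Sigma_e` up so the requested fractions are
fractions of the total.

The low-coverage dosage model is an idealized per-site imputer: reads are
`Poisson(depth)`, alternate-supporting reads `Binomial(reads, f)` with a
base-error rate, and the genotype posterior combines the read likelihood
with a Hardy-Weinberg prior at the site's empirical frequency; the dosage
is the posterior mean. It reproduces the qualitative behavior of real
imputation (accuracy rising with depth; prior-mean dosages at zero reads)
without modeling haplotype sharing, so its absolute accuracy at a given
depth is below that of LD-aware imputers.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: founder alleles are drawn independently per
site, so LD between markers is capped near `1/H` times the copying
persistence (`H` = founder pool size) rather than reaching the r2 ~ 0.5
of dense real maps at short range; there is no allele-frequency spectrum
skew, no genotyping error in the "truth" calls, no population structure
beyond founder sharing, and no missing-phenotype mechanism. Statistical
calibration (null uniformity of Wald p-values, coverage of drop-log(P)
intervals) transfers to real data only insofar as the model assumptions
(multivariate normality, a single genomic variance component) hold there.

# Validation problem sizes

The test suite and the acceptance script size their simulations to run on
a laptop-class single core in a few minutes while leaving the Monte Carlo
error well inside the asserted tolerances: heritability recovery uses
n = 500, m = 2000, 10 seeds (MAE tolerance 0.08); Wald calibration
n = 400, t = 3, 2000 SNPs; QTL-heritability recovery n = 500, 10 seeds
(tolerance 0.03 on the 10-seed mean); drop-log(P) coverage 100 replicates
of a 500-SNP region with 200 simulations each (coverage at least 90%); the
acceptance script re-runs scaled-down versions of the same computations.

# Known limitations

* One genomic variance component; no dominance, no GxE, no multiple random
  effects.
* Variance components are not re-estimated per SNP in the scans (standard
  practice, slightly conservative near very large QTL).
* `ld_prune()` approximates the reference pruning tool deterministically
  rather than bit-matching it.
* The exact HWE test is two-sided in the standard "sum of probabilities
  not exceeding the observed outcome" sense; no mid-p option.
* The drop-log(P) interval inherits the usual caveat of simulation-based
  CIs: it conditions on the observed lead SNP and its estimated effect.
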