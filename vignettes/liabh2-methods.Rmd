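---
title: "Estimating binary-trait heritability from genotypes and pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating binary-trait heritability from genotypes and pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liabh2)
```

## The model

`liabh2` treats a binary disease phenotype as a threshold exceedance of a
latent, unit-variance *liability*. With lifetime risk $K$, the threshold is
$t = \Phi^{-1}(1-K)$ and an individual is affected when liability $> t$. The
liability decomposes additively as

$$ l = g + e, \qquad g \sim N(0, h^2_l), \quad e \sim N(0, 1 - h^2_l), $$

so that $h^2_l$ — the narrow-sense heritability on the liability scale — is
the single quantity both estimation tracks target:

* **Genotype track.** Standardized SNP dosages define a genetic relationship
  matrix (GRM). The observed-scale (0/1) phenotypic variance is partitioned
  by AI-REML into a GRM component and a residual, and the observed-scale
  estimate is mapped to the liability scale with an ascertainment
  correction. PCGC regression — pairwise phenotype products regressed on GRM
  entries — re-estimates the same quantity without the REML scale
  conversion, as a bias cross-check.
* **Pedigree track.** The numerator relationship matrix $A$ built from
  pedigree structure replaces the GRM, and a Bayesian probit "animal" model
  with latent-liability data augmentation is fitted by Gibbs sampling. With
  the residual variance fixed at 1, each retained draw of the additive
  variance $\sigma^2_a$ yields $h^2 = \sigma^2_a / (\sigma^2_a + 1)$.

The genotype track estimates only the variance tagged by genotyped SNPs; the
pedigree track captures all additive genetic variance. Their gap is the
usual "missing heritability" of array-based designs.

### Liability-scale transformation

For a case-control sample with case fraction $P$ drawn from a population
with lifetime risk $K$, the observed-scale heritability $h^2_o$ maps to the
liability scale as

$$ h^2_l = h^2_o \; \frac{K^2 (1-K)^2}{z^2\, P (1-P)}, $$

where $z = \phi(t)$ is the standard-normal density at the threshold.
Standard errors transform by the same factor; with $P = K$ the factor
reduces to the unascertained $K(1-K)/z^2$. The transformation is linear in
$h^2_o$, which the test suite asserts exactly.

### Recurrence risk in relatives

Under the additive model the liabilities of two relatives with additive
relationship $a$ (0.5 for full siblings or parent–offspring) are standard
bivariate normal with correlation $r = a\,h^2_l$. The recurrence risk ratio
is

$$ \lambda = \frac{P(l_2 > t \mid l_1 > t)}{K}
           = \frac{P(l_1 > t,\, l_2 > t)}{K^2}, $$

computed by adaptive quadrature of
$\int_t^\infty \phi(x)\,\bar\Phi\!\big((t - r x)/\sqrt{1-r^2}\big)\,dx$ with
relative tolerance $10^{-10}$; a two-dimensional Simpson integration of the
bivariate density serves as the independent oracle in the tests (agreement
to $10^{-5}$ relative). At $K = 0.005$ the two heritability bounds the
package works with (0.374 from SNPs, 0.489 from pedigrees) give
$\lambda_s \approx 3.86$ and $5.46$:

```{r sibrr}
ctx <- liability_context(K = 0.005)
c(lower = sibling_rr(0.374, ctx), upper = sibling_rr(0.489, ctx))
```

`excess_familial_share()` divides the genetically explained excess
recurrence risk by the observed excess, $(\lambda_g - 1)/(\lambda_{obs}-1)$
— the definition is attached to the result as an attribute because other
decompositions exist and give materially different shares.

## AI-REML

`fit_reml()` maximizes the restricted likelihood of
$y \sim N(X\beta,\; \sum_c \sigma^2_c A_c + \sigma^2_e I)$. Updates use the
average-information matrix
$\mathrm{AI}_{cd} = \tfrac12 (Py)^\top A_c P A_d (Py)$ with the projection
matrix $P$; the first two iterations, and any AI step that fails or lowers
the restricted likelihood, fall back to EM. Numerical choices:

* **Variance floor** at $10^{-8} \times \mathrm{var}(y)$ instead of
  unconstrained estimates, keeping the liability transformation
  well-defined.
* **Starting values**: the phenotypic variance split equally across
  components — robust and unprejudiced.
* **Convergence**: successive restricted log-likelihood change below
  $10^{-6}$ (configurable).
* **Identifiability**: a GRM numerically indistinguishable from the
  identity leaves $\sigma^2_g$ and $\sigma^2_e$ confounded; the fit is
  flagged (`identifiable = FALSE`, `NA` standard errors) rather than
  reported with spurious precision.
* **Single-GRM fast path**: the model is rotated to the GRM eigenbasis,
  making each iteration $O(np^2)$ after one symmetric eigendecomposition.
  Small negative eigenvalues (possible with the GCTA diagonal convention)
  are floored at zero — a ridge on the order of numerical noise. The dense
  multi-GRM path and the fast path agree to $10^{-4}$ on exactly-PSD GRMs,
  which the tests assert.
* **Standard errors** come from the inverse AI matrix at convergence; CIs
  are Wald $\pm 1.96\,\mathrm{SE}$ on each scale, matching the symmetric
  intervals conventional for these analyses.

Case-control phenotypes enter as 0/1 with an intercept-only design by
default (no principal components — mirroring an analysis design where the
genomic inflation factor was modest).

Per-chromosome partitions fit one component per chromosome GRM
simultaneously. The whole-set single-GRM estimate is reported *alongside*
the per-chromosome total: the two need not agree and the package refuses to
force them to.

Per-SNP attribution follows the covariate-difference procedure: the joint
per-chromosome model is fitted with and without the SNP dosage appended as
a fixed covariate, and the SNP is credited with the drop in its own
chromosome's heritability. For a SNP with standardized effect $\beta$ this
recovers approximately $\beta^2$ of phenotypic variance, which the tests
verify against the single-locus formula.

## PCGC regression

With $P$ the sample case fraction, phenotypes are standardized to
$y^* = (y - P)/\sqrt{P(1-P)}$ and all $n(n-1)/2$ pairwise products
$y^*_j y^*_k$ are regressed through the origin on GRM entries. The slope is
mapped to the liability scale with the same ascertainment factor as above.
Standard errors are a delete-one-sample jackknife (removing all pairs that
involve the deleted sample; the case fraction is held fixed across
deletions). The covariate-free estimator is intentional — the cross-check
mirrors a covariate-free REML analysis.

## Pedigree track

`build_nrm()` applies Henderson's recursion in topological order
($A_{ii} = 1 + \tfrac12 A_{f(i),m(i)}$,
$A_{ji} = \tfrac12 (A_{j,f(i)} + A_{j,m(i)})$), and `nrm_inverse()`
assembles the sparse $A^{-1}$ directly from pedigree structure and
inbreeding coefficients. Both are validated against hand-computed values
(parent–offspring 0.5; the half-sib-mating offspring diagonal 1.125) and
against a 20,000-replicate gene-dropping Monte Carlo kinship estimate.

`fit_threshold_animal_model()` is a Gibbs sampler with data augmentation:

1. latent liabilities from truncated normal full conditionals (threshold
   fixed at 0; the intercept absorbs it — the standard identifiable
   parameterization);
2. fixed effects from their Gaussian full conditional;
3. breeding values by single-site updates over the sparse $A^{-1}$;
4. $\sigma^2_a$ from its scaled-inverse-chi-square full conditional
   (default prior df 1, scale 1, both configurable).

The residual variance is fixed at 1 (probit convention), so
$h^2 = \sigma^2_a/(\sigma^2_a + 1)$; the simulator generates data under the
same convention, making recovery tests internally consistent. Any
denominator convention of other animal-model software (e.g. treatment of
link variance) is deliberately not emulated; this package's convention is
the one stated here. The default chain — 1,100,000 rounds, 100,000 burn-in,
thinning 1,000, hence 1,000 retained samples — mirrors a registry-scale
analysis; tests use shorter chains.

Correctness of the full-conditional wiring is checked by disabling the
likelihood (`sample_prior = TRUE`): the chain must then reproduce the
scaled-inverse-chi-square prior, which a Kolmogorov–Smirnov test confirms.
Chain diagnostics report effective sample size (AR-based spectral density
at zero) and a Geweke z-score.

**Chain length matters more than it may appear.** On ~500-case simulated
designs a 30,000-round chain gave posterior means as far as 0.22 from a
converged longer chain on the same data; module tests therefore use at
least 60,000 rounds, and recovery at modest scale is judged on a
multi-dataset average because the dataset-to-dataset spread of the
posterior mean (SD ≈ 0.09–0.15 at 250–500 cases) dominates the Monte-Carlo
error of any single chain.

## The synthetic-data generators

The generators define the study conditions the estimators are tested under:

* **Genotypes**: independent SNPs with allele frequencies uniform on a
  configurable band (default 0.05–0.5), Hardy–Weinberg genotype
  proportions, missingness completely at random. No linkage disequilibrium
  and no X chromosome — so passing tests say nothing about LD-induced
  biases in real arrays.
* **Effects**: a seeded causal subset gets effects drawn
  $N(0, h^2/n_{causal})$ on the standardized scale and then rescaled so the
  population genetic variance equals $h^2$ exactly. The rescaling is the
  one departure from the plain infinitesimal draw: without it the realized
  heritability fluctuates with SD $h^2\sqrt{2/n_{causal}}$, which would
  contaminate every recovery tolerance with architecture noise that is not
  the object under test.
* **Ascertainment**: case-control samples are rejection-sampled jointly
  with their genotypes in batches — no genotype-free shortcut — keeping the
  genotype–liability coupling exact. A budget guard advises a larger $K$
  when quotas would need excessive batches (desk-scale tests use
  $K \ge 0.05$).
* **Pedigrees**: families start from a founder couple; each generation one
  child pairs with an unrelated immigrant and has a Poisson (truncated at
  1) number of children — so all individuals are non-inbred by
  construction, founders have genetic variance $h^2$, and offspring receive
  midparent values plus Mendelian deviates $N(0, h^2/2)$. Sibling liability
  correlation converges to $h^2/2$, which the tests verify at 25,000
  sib pairs. A default sibship mean of ~3 gives five-member nuclear
  families, comparable to registry family sizes.

Subtype labels are a seeded Bernoulli split among cases, supporting
stratified re-analysis as pure subsetting.

## Problem sizes used by the checks

The heavier validation checks run at sizes chosen to be informative yet
desk-scale: GREML recovery at $n = 2{,}000$, $m = 1{,}000$ over 10 seeds
(quantitative trait, true $h^2 = 0.4$); PCGC–GREML concordance on the same
design with a binary trait at $P = K = 0.2$ (the criterion fixes $P = K =
0.2$ but not the sample size; $n = 2{,}000$ is this package's choice);
pedigree recovery at 1,000 five-member nuclear families, $K = 0.05$, true
$h^2 = 0.5$, with 110,000-round chains and the posterior mean averaged over
two replicate datasets (a single ~250-case replicate has sampling SD ≈ 0.09,
so one draw would test luck, not recovery).

## Known limitations

* No LD structure, allele-frequency–effect coupling, or rare variants in
  the simulator; real-data biases from these are out of reach of the tests.
* PCGC is covariate-free; covariate-adjusted PCGC (per-individual
  thresholds) is not implemented.
* No ancestry/MDS sample exclusion — the QC sample filter covers call rate
  and heterozygosity only, since ancestry filtering needs external
  reference panels.
* No dominance or epistatic components anywhere: both tracks estimate
  narrow-sense (additive) heritability only.
* The per-SNP attribution inherits the noise of two REML fits; at
  desk-scale sample sizes individual-SNP attributions carry standard errors
  comparable to their values, exactly as in the published per-SNP tables.
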