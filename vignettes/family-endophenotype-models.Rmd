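---
title: "Variance components, BLUP endophenotypes and kinship-aware scans in extended families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance components, BLUP endophenotypes and kinship-aware scans in extended families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famendo)
```

## The model

famendo analyses quantitative traits measured on members of extended
families. The working model for a trait $y$ on $n$ relatives is the
polygenic mixed model

$$ y = X\beta + g + e, \qquad
   \operatorname{Cov}(y) = \sigma^2_g A + \sigma^2_e I, $$

where $A = 2\Phi$ is the additive relationship matrix ($\Phi$ the kinship
matrix), $g$ the additive genetic values and $e$ independent environmental
deviations. Heritability is $h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)$.
$A$ can come from a pedigree (`kinship_from_pedigree()`, the classic
recursion with founders at $\Phi_{ii} = 1/2$) or from a file holding an
empirical genomic relationship matrix (`read_grm()`), which is how studies
with whole-genome data sidestep cryptic relatedness.

For gene-expression traits the fitted model yields, per gene, the BLUP of
the genetic values,
$\hat g = \hat\sigma^2_g A \hat V^{-1}(y - X\hat\beta)$ — the
*endophenotype*: the heritable component of expression, stripped of most
environmental noise. Endophenotypes then enter kinship-aware association
scans as fixed-effect predictors of clinical phenotypes, evidence is pooled
across a phenotype set per gene by Fisher's combined test
($-2\sum_j \log p_j \sim \chi^2_{2k}$ under independence), and a
multivariate mixed model with Kronecker-structured covariance
($\Sigma_g \otimes A + \Sigma_e \otimes I$) provides a joint sensitivity
analysis across correlated traits.

## Numerical strategy

Every likelihood evaluation uses the spectral trick: with $A = U\Lambda U'$
computed once per relationship matrix, rotating $y$ and $X$ by $U'$ makes
the covariance diagonal, so for any candidate $h^2$ the fixed effects and
the total variance profile out in closed form (weighted least squares). The
profiled log-likelihood is maximized over $h^2 \in [0,1]$ with `optimize()`
(tolerance 1e-8), and both endpoints are evaluated explicitly so boundary
optima ($\hat h^2 = 0$ or $1$) are exact; a `boundary` flag is set within
1e-6 of either end. When all eigenvalues are equal (e.g. $A = I$, everyone
unrelated) the likelihood depends on the components only through their sum
and the fit carries `identifiable = FALSE`. The standard error of
$\hat h^2$ comes from a central finite difference of the profiled
log-likelihood (step 1e-4, one-sided at boundaries). Missing trait values
are handled by exact subsetting — the rotation is recomputed on the reduced
roster, never by imputation.

ML is the default estimator, REML is available; on the simulated designs
used in the tests the two agree to well under the sampling error
(|difference| < 0.02 at n = 1,000). The heritability test compares against
the $\sigma^2_g = 0$ null with the statistic referred to the half-and-half
mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, the correct reference when a
variance is pinned to its boundary; its null rejection rate is verified by
simulation (400 replicates) in the test suite.

The multivariate model is fitted after a second change of basis:
whitening by the Cholesky factor of $\Sigma_e$ and rotating by the
eigenvectors of $\Sigma_e^{-1}$-whitened $\Sigma_g$ decouples the traits,
so each evaluation costs $O(nT)$ after the one-off eigendecomposition.
$\Sigma_g$ and $\Sigma_e$ are parameterized by Cholesky factors
(log-diagonal) to stay positive semidefinite, optimized by BFGS with
multiple seeded starts (first start at the univariate fits), and fixed
effects are profiled exactly at every step. A dense Kronecker-covariance
likelihood evaluated by Cholesky factorization serves as the independent
oracle in the tests — it caught a transpose error in the whitening during
development, which is exactly what such oracles are for. The model is
capped at T = 6 traits to keep the parameter count sane.

## Normalization and phenotype preparation

Counts are normalized by geTMM: reads per kilobase first (removing
gene-length bias), then TMM scaling factors computed on the RPK matrix with
the canonical choices — reference sample by upper-quartile fraction closest
to the mean, 30% two-sided trim on M-values, 5% on A-values,
inverse-asymptotic-variance weights, factors rescaled to geometric mean 1 —
then per-million scaling and `log2(x + 0.5)`. The 0.5 offset keeps zeros
finite and is configurable. One subtlety the tests document: the *weighted*
trimmed mean is only approximately invariant to rescaling a single
sample's library (the precision weights depend on depth); the unweighted
variant (`weighted = FALSE`) is exactly invariant, and invariance under
rescaling all libraries together holds exactly either way.

Instrument batch effects are removed per gene by least squares on
sum-to-zero batch contrasts, optionally protecting biological covariates;
only the fitted batch terms are subtracted, so the operation is idempotent
and exact on additive shifts. Because the source protocol both disclaims
explicit batch correction and demonstrates a PCA-verified correction, the
pipeline makes correction an explicit switch (default on) and always emits
before/after PCA score tables so the diagnostic is visible either way.

Clinical traits are residualized on age, sex, age², sex×age and sex×age²
(sex coded 0/1), then inverse-normal transformed with the Blom offset
$z_i = \Phi^{-1}\!\big((r_i - 3/8)/(n + 1/4)\big)$, average ranks for ties.
The offset and the rank convention are the two things inverse-normal
implementations disagree on; both are exposed as arguments, and
residualize-then-transform is affine-invariant in the raw trait. Sex
differences are screened with the Mann–Whitney U test — exact enumeration
of all $\binom{n_a+n_b}{n_a}$ assignments for pooled n ≤ 12 (hard cap 20),
tie-corrected normal approximation with continuity correction otherwise.

## The synthetic-data generator

Because the motivating cohort's data are available only on request, every
stage is exercised on synthetic families with known ground truth.
`simulate_study()` generates: 20 extended families over 3 generations with
mean sibship 4.5 (about 30 members each, n ≈ 600 — the scale at which the
recovery tests operate); expression traits as $g + e$ with per-gene
$h^2 = 0.4$ by default, $g$ drawn through the symmetric factorization of
$A$; negative-binomial counts (global dispersion 0.1) whose log-mean adds
gene length, library size, and a two-level instrument batch offset
(0 / 0.5 on the log scale), emulating a two-sequencer design; and
liver/depression-style phenotypes (AST, ALT, AST/ALT, CAP, FAST, kPa,
BDI-II analogues) combining designated causal-gene effects (two pleiotropic
genes with opposite-signed effects on the depression analogue), an own
polygenic term ($h^2 = 0.35$, inside the 0.25–0.41 range reported for such
traits), the age/sex covariate terms, and noise; ages uniform 18–80. The
mating scheme marries every reproducing offspring to an unrelated immigrant
founder, so the pedigree is outbred and textbook kinship values hold
exactly; family-size spread beyond the Poisson sibship is not modelled, and
neither are genotypes, sequence reads, shared-household environments, or
ascertainment — so passing tests demonstrate correctness of the estimators
under the stated model, not robustness to everything real cohorts do.

Missing phenotype data (e.g. incomplete elastography) can be injected with
`missing_rate`, default off; all downstream stages drop missing values
pairwise per trait.

## Design choices worth knowing

- Endophenotypes enter the scan as measured fixed-effect predictors, the
  simplest reading of "independent variables"; full bivariate trait
  modelling of each (gene, phenotype) pair is out of scope.
- Fisher's combination assumes independent component tests. Liver traits
  are strongly inter-correlated, so combined p-values over such sets are
  anti-conservative and are best read as lower bounds; this is also why a
  naive combination of published per-trait p-values lands orders of
  magnitude below the published joint values, which evidently carry an
  additional (unstated) correction. The package reports the plain Fisher
  statistic and controls multiplicity across genes by Bonferroni and BH.
- The BLUP orthogonality property ($\operatorname{Cov}(\hat g, \hat g - g)
  = 0$) holds at the model's variance components; with plug-in estimates a
  small leakage of order the SE of $\hat h^2$ appears, which the tests
  measure around rather than pretend away.
- Loaded GRMs are symmetrized by averaging (warning above 1e-6 asymmetry);
  eigenvalues above $-10^{-8}\,\mathrm{tr}(A)$ are clipped to zero, more
  negative ones are an error.
- Enrichment uses the hypergeometric upper tail with universe = all
  annotated genes by default (configurable), one-sided over-representation
  only, BH FDR at 0.05.

## Problem sizes in the test suite

The suite runs at the sizes the methods are meant for while staying quick:
heritability recovery uses 25 replicate traits on one n ≈ 600 pedigree
(sharing its eigendecomposition — the replicated unit is the trait); null
calibration uses 400 LRT replicates and 500 null scan genes on the same
kinship; kinship is checked against a gene-dropping Monte Carlo oracle
(10^5 drops, per-entry Monte-Carlo standard errors) on pedigrees of ≤ 30;
the multivariate oracle checks run at T = 2 on ~80 individuals where the
dense Kronecker Cholesky is cheap. The whole suite completes in a few
minutes on one core.

## Limitations

No dominance, household, or gene-environment interaction components; no
genotype-level simulation or GRM estimation; no imputation; Fisher
combination is not dependence-corrected (a permutation-calibrated variant
is a natural extension); and results on real annotation databases depend on
the annotation release, which is why enrichment is tested only on seeded
synthetic collections.
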