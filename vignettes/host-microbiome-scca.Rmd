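---
title: "Modelling host-microbiome association with Tweedie abundances and sparse CCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling host-microbiome association with Tweedie abundances and sparse CCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(tweediecca)
```

## The problem

Genome-wide association studies of the gut microbiome usually test one
variant against one taxon at a time, which discards the aggregate,
many-small-effects structure that is plausible for a complex community
phenotype. `tweediecca` takes the multivariate route: it asks which *sets*
of host variants and which *sets* of microbial features (gene families or
species) share a common latent factor, using sparse canonical correlation
analysis (sCCA). Around that core it implements the preprocessing such an
analysis needs to be credible on shotgun metagenomic data from a twin
cohort: compositionality-aware normalization, Tweedie modelling of
zero-inflated abundances, genotype quality control, and mixed-model removal
of covariate and relatedness effects.

## Normalization: modified RPKM

Shotgun sequencing yields relative abundances: each sample's counts are
constrained by its library size, so naive correlations are distorted. We
divide each count by the gene length in kilobases and by the sample's
geometric mean of counts — a hybrid of RPKM and a centred-log-ratio-style
correction, applied without logs so zeros remain exact zeros:

$$y_{ij} = \frac{c_{ij}}{(\ell_i/1000)\; g_j}, \qquad
  g_j = \exp\Big(\tfrac{1}{|P_j|}\sum_{i \in P_j} \log c_{ij}\Big),$$

where $P_j$ is the set of features with positive counts in sample $j$.
Species tables, which have no meaningful length, are divided by $g_j$ only.

Two deliberate choices:

* **Zeros and the geometric mean.** The geometric mean is taken over the
  strictly positive entries, with no pseudocount. This preserves the key
  compositional contract — multiplying every count in a sample by a
  constant leaves the normalized sample unchanged — which any pseudocount
  would break. The tests assert this invariance on random tables.
* **Length unit.** Per-kilobase, matching the RPKM convention. The absolute
  scale is irrelevant downstream: residualization and CCA are equivariant
  to per-feature scaling.

Features are then kept only if present (nonzero) in at least 10% of
samples, boundary inclusive.

## The Tweedie model for normalized abundances

After normalization the values are continuous, nonnegative, right-skewed,
and zero-inflated — outside the reach of Poisson or negative-binomial
models, whose support is integer counts and whose log-variance/log-mean
relationship is fixed at intercept zero. The Tweedie compound
Poisson-gamma family with power $1 < p < 2$ has exactly the right support
(a point mass at zero plus a continuous positive density) and a free
power-law mean-variance relationship

$$\mathrm{Var}(Y) = \phi\,\mu^p, \qquad
  P(Y = 0) = \exp\!\Big(\frac{-\mu^{2-p}}{\phi(2-p)}\Big).$$

The power is estimated from the data by Taylor's law: across features,
ordinary least squares of $\log(\mathrm{var})$ on $\log(\mathrm{mean})$
gives $p$ as the slope and $\log\phi$ as the intercept
(`estimate_taylor_power()`). Features with zero mean or zero variance are
excluded, not imputed. A single global $(p, \phi)$ is fitted per table;
per-feature dispersion is re-estimated inside each downstream model fit.
OLS on logs is the default (likelihood profiling of $p$ would be a
possible extension; the log-log fit is transparent, fast, and is what the
mean-variance diagnostic plots display). `zero_diagnostic()` compares each
feature's observed zero fraction with the fitted $P(Y=0)$ at its mean; an
adequate fit puts features on the diagonal.

```{r tweedie-example}
set.seed(1)
tab <- t(vapply(runif(300, 0.5, 20),
                function(m) sample_tweedie(150, m, phi = 2, p = 1.6),
                numeric(150)))
dimnames(tab) <- list(sprintf("f%03d", 1:300), sprintf("s%03d", 1:150))
fit <- estimate_taylor_power(feature_table(tab))
fit
```

## Genotype preprocessing

Filters mirror the strictest common practice for an association analysis
of this size, in a fixed order (each filter is idempotent):

1. **Missingness**: any locus with a missing call is dropped (`--geno 0`).
2. **MAF**: minor allele frequency $\min(f, 1-f) \ge 0.10$, boundary
   inclusive.
3. **HWE**: 1-df chi-square goodness of fit of genotype counts against
   $n(1-f)^2, 2nf(1-f), nf^2$; loci with $p < 0.001$ dropped. The plain
   chi-square (not the exact test) is used; monomorphic loci are
   untestable and dropped with a warning.
4. **LD pruning**: sliding 50-locus windows advancing by 10; while any
   surviving pair exceeds $r^2 = 0.8$, the lower-MAF member is removed
   (tie: later position). Passes repeat until the retained set passes an
   exhaustive within-window check, making the rule determinate where
   plink leaves it implementation-defined.

Each surviving locus is coded as two columns: additive $\{1, 0, -1\}$ for
0/1/2 copies of the minor allele and dominance $\{-1, 1, -1\}$
(heterozygote $= 1$, the standard coding that is orthogonal to the
additive term on a 1/4:1/2:1/4 genotype-balanced sample). The two columns
form one selection group so a variant is selected or dropped as a whole.
The dominance mapping order follows the orthogonal-coding convention:
heterozygotes receive the $+1$.

Ancestry principal components are fitted on one representative per family
(lowest-sorting sample id, for reproducibility) so duplicated MZ genotypes
cannot distort the eigenstructure, and all samples — including the held-out
co-twins — are then scored on those loadings.

## Residualization

Covariates (age at sampling, BMI, shipment batch, ten ancestry PCs) and
twin relatedness must not leak into the canonical correlations. Both data
sides are residualized with mixed models sharing one fixed-effect design:

* **Abundances**: per feature, a Tweedie GLMM with log link, the global
  power $p$, and a random intercept per twin pair, fitted by penalized
  quasi-likelihood. The inner step of the IRLS loop is a generalized
  least-squares solve that exploits the pair structure (the marginal
  covariance is block diagonal with 1x1 and 2x2 blocks, so $V^{-1}$ is
  closed-form); variance components are moment estimates from the
  within-pair covariance of working residuals, damped and frozen after a
  burn-in so the loop converges against a fixed covariance (maximum 100
  iterations, relative deviance change below $10^{-8}$). Pearson
  residuals $(y - \hat\mu)/\hat\mu^{p/2}$ are returned, centered;
  variance-standardized residuals are the natural input for a correlation
  analysis (response or deviance residuals are reasonable alternatives,
  but Pearson keeps the mean-variance correction explicit). Features whose
  mixed fit fails fall back to fixed family intercepts; failing both they
  are dropped and recorded in the `exclusions` attribute.
* **Genotype columns**: the Gaussian analogue, returning conditional
  residuals (observed minus fixed effects minus family BLUP). These are
  exactly orthogonal to the fixed-effect design — a property the tests
  assert at $10^{-6}$.

A cohort of unrelated individuals is the degenerate case: with all-distinct
family ids there are no pairs, the family variance is zero, and both fits
reduce to ordinary (G)LM residuals — also a regression test.

The random intercept is per *twin pair* (family), not per zygosity class:
a two-level zygosity effect cannot absorb within-pair correlation. Note
what this residualization implies for power: an MZ pair's genotype columns
are identical within the pair, so the family intercept absorbs nearly all
of their genotype variance; association signal is carried mainly by DZ
within-pair contrasts and the part of between-family variation the BLUP
shrinkage leaves behind. This is the price of treating the cohort as
unrelated, and it is shared by any design that removes relatedness before
a correlation analysis.

## Sparse CCA

With residual matrices $X$ (samples x coded genotype columns) and $Y$
(samples x features), the model solves

$$\operatorname*{argmin}_{\alpha,\beta:\; \|X\beta\|_2 = \|Y\alpha\|_2 = 1}
  \|X\beta - Y\alpha\|_2^2
  + \lambda_1 \sum_g \|\beta_g\|_2
  + \lambda_2 \Big(m \|\alpha\|_1 + \tfrac{1-m}{2}\|\alpha\|_2^2\Big)$$

— a group lasso over each locus's additive/dominance pair (selecting
variants as wholes) and an elastic net over features (selecting correlated
feature groups together rather than one arbitrary representative). The
optimization is block coordinate descent: alternately regress the current
$Y$-variate on $X$ under the group-lasso penalty and the $X$-variate on
$Y$ under the elastic net, rescaling each fitted variate to unit norm
after its half-step, until the relative objective change drops below
$10^{-6}$. Each penalized regression is solved by FISTA (proximal gradient
with momentum); the group prox is blockwise soft-thresholding, and the
unpenalized low-dimensional limit is verified in the tests against
classical CCA (`stats::cancor`) to $10^{-4}$, with KKT-condition checks
and an independent coordinate-descent solver as oracles for the penalized
steps.

Numerical choices worth stating:

* **Initialization** is deterministic: the leading singular vector of
  $Y^\top X$ (computed matrix-free by power iteration), so repeated runs
  agree bit-for-bit.
* **Penalty grid**: twelve pairs, 3 group-lasso x 4 elastic-net values
  log-spaced from 1% to 100% of each side's analytic maximum (the
  smallest penalty that zeroes that side at the initialization). The grid
  is tuned once by 5-fold cross-validation on held-out variate
  correlation; ties favor the sparser pair. The chosen pair is reused for
  subsequent components. With twin data, whole families are assigned to
  folds: if co-twins straddled a train/test split, any residual
  within-family correlation would let overfit fits score spuriously well
  on held-out co-twins. CV fits are deliberately coarse (10 alternations,
  50 inner iterations, warm-started across the grid) — the held-out
  ranking of penalty pairs stabilizes long before full convergence, and
  the final component is refitted at full precision.
* **Elastic-net mixing** defaults to $m = 0.5$, an even balance between
  selection and grouping.
* **Deflation**: after a component is accepted, every column of each
  matrix is regressed on that matrix's *own* canonical variate and
  replaced by the residual (Witten-style deflation; regressing on the
  other side's variate is exposed nowhere because the selected convention
  keeps each matrix's geometry self-contained). Deflated columns are
  orthogonal to the extracted variate at $10^{-8}$.
* **Final refit**: classical CCA on the selected columns only; when the
  selection approaches the sample count, covariance blocks get a
  $10^{-3}$ ridge on the diagonal.
* **Interpretation rule**: weights are reported but flagged
  selection-only. Shrinkage makes magnitudes incomparable across features,
  so downstream analysis should read them as zero vs nonzero.

## The synthetic twin cohort

Because the motivating cohort is access-controlled, validation rests on a
simulator that reproduces the data-generating assumptions end to end:

* **Genotypes** from explicit haplotypes: a Gaussian copula with
  equicorrelation 0.95 inside 10-locus LD blocks thresholds to alleles at
  each locus's MAF (drawn uniformly on 0.05-0.5), so marginal frequencies
  are exact and founders are in exact HWE. MZ pairs (28% of 150 pairs,
  matching a predominantly-DZ registry cohort) duplicate one genotype; DZ
  pairs inherit one haplotype per parent per block, giving expected 1/2
  identity by descent — realistic enough that family random effects are
  genuinely testable.
* **Latent factor**: the standardized sum of ten planted SNP dosages plus
  Gaussian noise (SD 0.3), standardized. Planted loci are placed one per
  widely-spaced block with common-variant MAFs (0.2-0.45), the regime in
  which an association design of this size has power.
* **Abundances**: per feature, log-mean = baseline (log-normal across
  features) + 0.5 x latent factor for the twenty planted features +
  covariate terms (age 0.01 per year, BMI 0.02 per unit, batch offsets
  with SD 0.2) + a per-family intercept (SD 0.3); counts are Tweedie
  draws ($p = 1.6$, $\phi = 2$) scaled by gene length so the
  modified-RPKM step is exercised. The Taylor-law estimator recovers the
  configured $(p, \phi)$ from generated tables — the loop-closure test
  between the simulator and the estimator.
* All randomness flows through one seeded stream: identical configuration
  and seed give a bit-identical cohort.

What the simulator does *not* emulate: real LD is block-irregular with
long-range structure; real abundances have feature-feature correlation
beyond the single planted factor (cross-feeding, shared pathways);
covariate effects are feature-specific in reality but global scalars
here; and there is no population stratification unless configured.
Passing recovery tests therefore demonstrates that the machinery works
under its own assumptions, not that any particular biological finding
would replicate.

## Validation workloads and problem sizes

The reference validation cohort is 150 pairs (300 samples), 2,000 loci,
1,000 features, effect 0.5, seed 20220309 — large enough that sparse
selection is a genuine high-dimensional problem ($p \gg n$ on the
genotype side after coding), small enough for a desk run. Recovery is
scored with LD-aware tagging: a planted locus counts as found if a
selected locus tags it at $r^2 > 0.8$ (the pruning threshold), and a
selected locus is a false selection only if it tags no planted locus —
the standard convention when pruning may keep a proxy rather than the
planted variant itself. Stability is checked the way the original
analysis did it: rerun the selection on abundance-side sample
permutations and measure how little of the real selection reappears.
Monte-Carlo checks (moments of the Tweedie sampler, HWE type-I rates) use
3-sigma bounds at their stated sizes.

An honest caveat on what the end-to-end run shows. At the reference
conditions the per-variant association with the latent factor, *after*
twin residualization, sits essentially at the extreme-value noise ceiling
of ~1,750 candidate locus groups at $n = 300$ (correlations of 0.24-0.32
against a ceiling of ~0.28), and the per-cell cross-correlations
(~0.07) are far below the $\sqrt{\log(pq)/n}$ threshold any
initialization scheme would need to locate the planted block. In this
$p \gg n$ regime both penalized regressions can interpolate any proposed
variate in sample, so the alternating objective cannot distinguish the
planted support from overfit directions — a power limit of this class of
method under relatedness-removing residualization, not a solver issue
(the solvers are verified against KKT conditions, independent
implementations, and the classical-CCA limit, and planted recovery
succeeds in the direct sCCA fixtures whose per-variable signal is above
threshold). The end-to-end suite therefore reports partial support
recovery at the reference conditions; the null-cohort (selection
unrelated to planted labels) and permutation-stability checks are the
end-to-end properties that hold. Practitioners should read this as a
genuine statement about power: with ~150 effective twin pairs, an
aggregate latent effect of 0.5 on the log-mean spread over five variants
is at the edge of what penalized selection can identify.

## Known limitations

* Variance components are moment estimates, not REML; they are accurate
  enough for residualization (the dense mixed-model-equation oracle and
  lme4 agree in the tests) but should not be read as heritability
  estimates — which the package deliberately does not report.
* No inference on sCCA coefficients: standard errors under selection are
  unavailable, so there are no p-values on weights, only the selection
  sets, their cross-validated correlation, and enrichment of the selected
  sets (two-sided Fisher's exact test with Benjamini-Hochberg FDR,
  reported at the FDR < 0.1 convention).
* Two-table CCA only; more than two data modes would need a different
  deflation scheme.
* The Tweedie power is clamped to $[1.05, 1.95]$ for the GLMM stage if
  the Taylor fit strays outside the zero-inflated regime, with a warning.

## A note on package shape

Result-like objects (tidy weight tables, CV tables, enrichment results,
`tidy()`/`glance()` methods, `autoplot()`s) are tibble- and
ggplot2-native; the large numeric containers (feature tables, genotype
matrices, residual matrices) are matrix-backed S3 classes, as is usual
for multivariate omics packages — a samples x 2,000-locus matrix is not
usefully a data frame.
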