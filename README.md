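# tweediecca

Collective association between host genetic variants and gut-microbiome
features, for statistical geneticists and microbiome researchers with
paired genotype + shotgun-metagenomic data. Instead of testing one SNP
against one taxon at a time, `tweediecca` finds *sets* of variants and
*sets* of microbial gene families or species whose linear combinations are
maximally correlated — sparse canonical correlation analysis (sCCA) with
penalties matched to each data type — on top of a preprocessing stack
built for zero-inflated, compositional metagenomic abundances in a twin
cohort.

## The model

Abundances are normalized by a **modified RPKM**: each count is divided by
gene length (kb) and by the sample's geometric mean of positive counts,
correcting library size and compositionality in one step while keeping
zeros exact. Normalized abundances are modelled as **Tweedie** compound
Poisson–gamma variables (power `1 < p < 2`):

    Var(Y) = phi * mu^p,      P(Y = 0) = exp(-mu^(2-p) / (phi * (2-p)))

with `p` estimated from Taylor's law (the log-variance vs log-mean
regression across features). Genotypes pass missingness / MAF ≥ 0.10 /
HWE (p ≥ 0.001) / LD (r² ≤ 0.8, 50-10 windows) filters and are coded per
locus as additive {1, 0, −1} plus dominance {−1, 1, −1} columns. Both
sides are residualized against age, BMI, shipment batch, ten ancestry PCs
and a random intercept per twin pair (Tweedie GLMM for abundances,
Gaussian LMM for genotypes). The residual matrices X (genotype) and Y
(abundance) then enter

    argmin ||X b - Y a||^2 + l1 * sum_g ||b_g||_2
                           + l2 * (m ||a||_1 + (1-m)/2 ||a||_2^2)
    subject to ||X b|| = ||Y a|| = 1

— group lasso selecting whole variants, elastic net selecting correlated
feature groups — solved by block coordinate descent, with a 12-pair
penalty grid tuned by 5-fold cross-validation, matrix deflation for
further components, and a classical CCA refit on the selected columns.
Selected feature sets can be tested for pathway enrichment (two-sided
Fisher's exact test, Benjamini–Hochberg FDR).

A seeded twin-cohort simulator (`simulate_cohort()`) generates genotypes
with LD blocks and exact founder HWE, MZ/DZ twin structure, covariates,
and Tweedie abundances carrying a planted SNP→feature latent factor, so
the whole pipeline can be validated against known truth.

## Worked example

```r
library(tweediecca)

coh <- simulate_cohort(simulation_config(
  n_pairs = 60, n_loci = 300, n_features = 100,
  n_planted_snps = 5, n_planted_features = 15, seed = 11))

res <- run_pipeline(coh$genotypes, coh$abundances, coh$covariates,
                    annotation = coh$annotation, seed = 42)
res
selection_scores(res$model, coh)
```

The pipeline prints stage-by-stage counts and the fitted Tweedie power,
then the model summary. The run above prints:

```
normalized 100 features (modified_rpkm)
100 features at prevalence >= 0.1
Tweedie fit: p = 1.694, phi = 1.294
loci surviving filters: 300 -> 270 -> 269 -> 265
residualizing 100 features (Tweedie GLMM, p = 1.694) and 530 coded columns
<tweediecca_pipeline>
<scca_model> 2 component(s)
  [1] cor = 0.972 | 2 loci, 86 features (l1 = 0.496, l2 = 0.102)
  [2] cor = 0.984 | 2 loci, 83 features (l1 = 0.496, l2 = 0.102)
  feature union across components: 98 (98.00%)
```

`cor` is each component's canonical correlation after the classical-CCA
refit on the selected columns; `l1`/`l2` are the cross-validated group
lasso and elastic-net penalties; the locus and feature counts are the
selected sets (weights should be read as zero vs nonzero only). Note the
in-sample canonical correlations are near 1 and the feature selection is
dense: at 120 samples the held-out tuning keeps permissive penalties, and
an aggregate latent effect of 0.5 spread over five variants is at the
edge of what penalized selection can identify once twin relatedness is
removed — the methods vignette quantifies this power limit.
`selection_scores()` compares the pooled selections with the simulator's
planted truth (recall and false-selection rate, crediting LD proxies at
r² > 0.8). `tidy(res$model)` returns the full weight/selection table,
`glance(res$model)` the per-component summary, and
`autoplot(res$model)` the cross-validation surface.
`permute_check(res, 2)` reruns the selection on permuted abundance rows
and reports how much of the real selection reappears.

A thin command-line wrapper with `simulate` / `run` / `permute`
subcommands is installed at `inst/scripts/tweediecca`.

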