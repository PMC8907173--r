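Package: tweediecca
Title: Host-Microbiome Association by Tweedie Modelling and Sparse Canonical Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects collective associations between host genetic variants and
    gut-microbiome features. Metagenomic gene-family or species abundance tables
    are normalized with a compositionality-aware modified RPKM (per-sample
    geometric mean), modelled with the Tweedie compound Poisson-gamma
    distribution (Var(Y) = phi * mu^p), and residualized against covariates,
    ancestry and twin relatedness with Tweedie and Gaussian mixed models.
    Genotypes are quality-filtered (missingness, MAF, Hardy-Weinberg, LD
    pruning) and coded for additive and dominance effects. The two residual
    matrices are then related by sparse canonical correlation analysis with a
    group-lasso penalty on variants and an elastic-net penalty on microbial
    features, with cross-validated penalty tuning, matrix deflation for
    additional components, and a final classical CCA refit on the selected
    features. Selected feature sets can be tested for pathway enrichment with
    Fisher's exact test and Benjamini-Hochberg FDR control. A twin-cohort
    simulator with planted SNP-feature latent associations provides ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    generics,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
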