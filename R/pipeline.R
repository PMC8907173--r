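#' Pipeline parameter set
#'
#' Defaults mirror the reference analysis settings: prevalence filter 10%,
#' genotype filters geno 0 / MAF 0.10 / HWE 0.001 / LD 50-10-0.8, ten
#' ancestry PCs, two canonical components, five CV folds, elastic-net
#' mixing 0.5.
#'
#' @param prevalence Minimum feature prevalence.
#' @param min_maf Minimum minor allele frequency.
#' @param hwe_alpha Hardy-Weinberg rejection level.
#' @param ld_window,ld_step,ld_r2 LD pruning controls.
#' @param k_pcs Ancestry principal components.
#' @param n_components Canonical components to extract.
#' @param folds Cross-validation folds.
#' @param mixing Elastic-net mixing.
#' @param fdr_cutoff Enrichment reporting threshold.
#' @return A named list of parameters.
#' @export
pipeline_params <- function(prevalence = 0.10, min_maf = 0.10,
                            hwe_alpha = 0.001, ld_window = 50L,
                            ld_step = 10L, ld_r2 = 0.8, k_pcs = 10L,
                            n_components = 2L, folds = 5L, mixing = 0.5,
                            fdr_cutoff = 0.1) {
  as.list(environment())
}

#' Run the full association workflow
#'
#' Normalize (modified RPKM when lengths are present, per-sample geometric
#' mean otherwise) and prevalence-filter the abundance table; fit the
#' Tweedie power; filter, code and residualize the genotypes; residualize
#' the abundances; run sparse CCA; and, when an annotation map is given,
#' test the pooled selected features for term enrichment. Stage-by-stage
#' feature and locus counts are collected in the returned manifest.
#'
#' @param genotypes A [genotype_matrix()].
#' @param abundances A raw [feature_table()].
#' @param covariates Covariate table (see [validate_covariates()]).
#' @param annotation Optional feature-to-term map for enrichment.
#' @param params A [pipeline_params()] list.
#' @param seed Integer seed for the cross-validation splits.
#' @return A `tweediecca_pipeline` list: normalized/filtered tables, the
#'   Tweedie fit, residual matrices, the `scca_model`, a selection summary,
#'   optional enrichment table, and a manifest of parameters, seed and
#'   stage counts.
#' @export
run_pipeline <- function(genotypes, abundances, covariates,
                         annotation = NULL, params = pipeline_params(),
                         seed = 1L) {
  if (params$n_components < 1L) stop("n_components must be at least 1")
  covariates <- validate_covariates(covariates)
  counts_log <- list(n_features_raw = nrow(abundances),
                     n_loci_raw = ncol(genotypes))

  norm <- if (!is.null(attr(abundances, "lengths"))) {
    normalize_modified_rpkm(abundances)
  } else {
    normalize_geometric_mean(abundances)
  }
  message("normalized ", nrow(norm), " features (",
          attr(norm, "normalization"), ")")
  filt <- prevalence_filter(norm, params$prevalence)
  counts_log$n_features_prevalent <- nrow(filt)
  message(nrow(filt), " features at prevalence >= ", params$prevalence)

  tfit <- estimate_taylor_power(filt)
  p_use <- min(max(tfit$p, 1.05), 1.95)
  if (p_use != tfit$p) {
    warning(sprintf(
      "fitted Tweedie power %.2f clamped to %.2f for the GLMM stage",
      tfit$p, p_use))
  }
  message(sprintf("Tweedie fit: p = %.3f, phi = %.3f", tfit$p, tfit$phi))

  g <- filter_geno_missing(genotypes)
  counts_log$n_loci_complete <- ncol(g)
  g <- filter_geno_maf(g, params$min_maf)
  counts_log$n_loci_maf <- ncol(g)
  g <- filter_geno_hwe(g, params$hwe_alpha)
  counts_log$n_loci_hwe <- ncol(g)
  g <- ld_prune(g, params$ld_window, params$ld_step, params$ld_r2)
  counts_log$n_loci_pruned <- ncol(g)
  message("loci surviving filters: ",
          paste(unlist(counts_log[c("n_loci_complete", "n_loci_maf",
                                    "n_loci_hwe", "n_loci_pruned")]),
                collapse = " -> "))

  k_eff <- min(params$k_pcs, ncol(g))
  cov <- covariates[match(rownames(g), covariates$sample_id), ]
  if (anyNA(cov$sample_id)) stop("covariates missing for some samples")
  if (k_eff > 0) {
    pcs <- ancestry_pcs(g, k = k_eff, family_ids = cov$family_id)
    cov <- dplyr::bind_cols(cov, tibble::as_tibble(pcs))
  }
  coded <- code_additive_dominance(g)

  message("residualizing ", nrow(filt), " features (Tweedie GLMM, p = ",
          round(p_use, 3), ") and ", ncol(coded), " coded columns")
  yres <- tweedie_glmm_residuals(filt, cov, p = p_use)
  xres <- gaussian_lmm_residuals(coded, cov)

  model <- run_scca(xres, yres, n_components = params$n_components,
                    folds = params$folds, seed = seed,
                    mixing = params$mixing, family_id = cov$family_id)
  summary_tbl <- glance.scca_model(model)
  sel <- lapply(model$components, function(x) x$selected_features)
  overlap_tbl <- NULL
  if (length(sel) >= 2) {
    overlap_tbl <- selection_summary(length(sel[[1L]]), length(sel[[2L]]),
                                     length(intersect(sel[[1L]],
                                                      sel[[2L]])),
                                     nrow(filt))
  }
  enrich <- NULL
  if (!is.null(annotation) && length(unlist(sel)) > 0) {
    enrich <- fisher_enrichment(unique(unlist(sel)), rownames(filt),
                                annotation,
                                fdr_cutoff = params$fdr_cutoff)
  }
  structure(list(normalized = filt, tweedie_fit = tfit,
                 genotypes_filtered = g, coded = coded,
                 covariates = cov, abundance_residuals = yres,
                 genotype_residuals = xres, model = model,
                 component_summary = summary_tbl,
                 selection_overlap = overlap_tbl,
                 enrichment = enrich,
                 manifest = list(params = params, seed = seed,
                                 tweedie_p_used = p_use,
                                 counts = counts_log,
                                 package_version =
                                   as.character(utils::packageVersion(
                                     "tweediecca")))),
            class = "tweediecca_pipeline")
}

#' @export
print.tweediecca_pipeline <- function(x, ...) {
  cat("<tweediecca_pipeline>\n")
  print(x$model)
  if (!is.null(x$selection_overlap)) {
    cat(sprintf("  feature union across components: %d (%.2f%%)\n",
                x$selection_overlap$n_union,
                x$selection_overlap$pct_union))
  }
  invisible(x)
}

#' Stability check by sample-label permutation
#'
#' Permutes the sample rows of the abundance residual matrix, reruns the
#' sparse selection with the penalty pairs chosen on the unpermuted data,
#' and reports the fraction of the real run's selections that reappear. A
#' small overlap indicates the real selections are not an artifact of the
#' selection machinery.
#'
#' @param result A `tweediecca_pipeline` from [run_pipeline()].
#' @param n_permutations Number of permuted reruns (0 gives an empty
#'   report).
#' @param seed Integer seed for the permutations.
#' @return Tibble with one row per permutation: overlap fractions for SNP
#'   and feature selections.
#' @export
permute_check <- function(result, n_permutations = 2L, seed = 1L) {
  stopifnot(inherits(result, "tweediecca_pipeline"))
  if (n_permutations < 1L) {
    return(tibble::tibble(permutation = integer(0),
                          snp_overlap = numeric(0),
                          feature_overlap = numeric(0)))
  }
  model <- result$model
  real_snps <- unique(unlist(lapply(model$components,
                                    function(x) x$selected_snps)))
  real_feats <- unique(unlist(lapply(model$components,
                                     function(x) x$selected_features)))
  X <- unclass(result$genotype_residuals)
  Y <- unclass(result$abundance_residuals)
  groups <- attr(result$genotype_residuals, "groups")
  perms <- with_local_seed(seed, {
    lapply(seq_len(n_permutations),
           function(i) sample.int(nrow(Y)))
  })
  purrr::imap_dfr(perms, function(prm, i) {
    Yp <- Y[prm, , drop = FALSE]
    Xc <- scale(X, scale = FALSE); Yc <- scale(Yp, scale = FALSE)
    snps <- character(0); feats <- character(0)
    for (ci in seq_along(model$penalty_pairs)) {
      pen <- model$penalty_pairs[[ci]]
      comp <- scca_fit(Xc, Yc, groups, pen["lambda1"], pen["lambda2"],
                       mixing = model$mixing, max_iter = 50L,
                       inner_max_iter = 300L)
      if (comp$status != "ok") break
      snps <- union(snps, comp$selected_snps)
      feats <- union(feats, comp$selected_features)
      if (ci < length(model$penalty_pairs)) {
        defl <- deflate(Xc, Yc, comp)
        Xc <- defl$Xres; Yc <- defl$Yres
      }
    }
    tibble::tibble(permutation = i,
                   snp_overlap = selection_overlap(real_snps, snps),
                   feature_overlap = selection_overlap(real_feats, feats))
  })
}
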