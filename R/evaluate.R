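#' Score a fitted model against a synthetic cohort's planted truth
#'
#' Computes recall and false-selection rate for the planted SNP groups and
#' planted features, pooling selections across components. Because LD
#' pruning may keep a near-perfect proxy instead of the planted locus
#' itself, a planted SNP counts as recovered if any selected locus tags it
#' at squared correlation above `r2_tag`, and a selected locus counts as a
#' false selection only if it tags no planted locus.
#'
#' @param model An `scca_model` from [run_scca()].
#' @param cohort The `synthetic_cohort` the model was fitted to.
#' @param r2_tag LD-tagging threshold; default 0.8 (the pruning threshold).
#' @return One-row tibble: `snp_recall`, `snp_fsr`, `feature_recall`,
#'   `feature_fsr`, and the selected-set sizes.
#' @export
selection_scores <- function(model, cohort, r2_tag = 0.8) {
  stopifnot(inherits(model, "scca_model"),
            inherits(cohort, "synthetic_cohort"))
  sel_snps <- unique(unlist(lapply(model$components,
                                   function(x) x$selected_snps)))
  sel_feats <- unique(unlist(lapply(model$components,
                                    function(x) x$selected_features)))
  planted_snps <- cohort$truth$planted_snps
  planted_feats <- cohort$truth$planted_features
  calls <- unclass(cohort$genotypes)
  tags_planted <- function(locus) {
    if (locus %in% planted_snps) return(TRUE)
    r2 <- suppressWarnings(
      stats::cor(calls[, locus],
                 calls[, planted_snps, drop = FALSE]))^2
    any(r2 > r2_tag, na.rm = TRUE)
  }
  planted_hit <- vapply(planted_snps, function(pl) {
    if (pl %in% sel_snps) return(TRUE)
    if (length(sel_snps) == 0) return(FALSE)
    r2 <- suppressWarnings(
      stats::cor(calls[, pl], calls[, sel_snps, drop = FALSE]))^2
    any(r2 > r2_tag, na.rm = TRUE)
  }, logical(1))
  snp_false <- if (length(sel_snps) == 0) 0 else {
    sum(!vapply(sel_snps, tags_planted, logical(1)))
  }
  tibble::tibble(
    snp_recall = mean(planted_hit),
    snp_fsr = if (length(sel_snps) == 0) 0
              else snp_false / length(sel_snps),
    feature_recall = mean(planted_feats %in% sel_feats),
    feature_fsr = if (length(sel_feats) == 0) 0
                  else mean(!(sel_feats %in% planted_feats)),
    n_selected_snps = length(sel_snps),
    n_selected_features = length(sel_feats))
}

#' Overlap of two selection sets
#'
#' Fraction of the reference selection that reappears in another run's
#' selection — the stability measure used when rerunning on permuted data.
#'
#' @param reference,other Character vectors of selected identifiers.
#' @return Overlap fraction in `[0, 1]` (1 when `other` reproduces the
#'   reference exactly; 0 for an empty reference).
#' @export
selection_overlap <- function(reference, other) {
  if (length(reference) == 0) return(0)
  mean(reference %in% other)
}
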