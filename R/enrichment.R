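#' Pathway enrichment of a selected feature set
#'
#' For every annotation term, builds the 2x2 contingency table of selected
#' vs background features against term membership and applies a two-sided
#' Fisher's exact test, followed by Benjamini-Hochberg FDR correction across
#' the terms tested. The background universe is caller-supplied (e.g. all
#' features, or all features with any annotation), mirroring the convention
#' of testing against "all pathways present in the samples".
#'
#' @param selected Character vector of selected feature identifiers
#'   (subset of `background`).
#' @param background Character vector: the feature universe.
#' @param annotation Data frame with columns `feature_id` and `term`
#'   (one row per feature-term link; multi-term features count once per
#'   term); optionally `term_name`.
#' @param fdr_cutoff Reporting threshold on the BH q-value recorded in the
#'   `significant` column; default 0.1.
#' @return Tibble, one row per term, sorted by q-value: the four 2x2 counts
#'   (`n_selected_term`, `n_selected_other`, `n_background_term`,
#'   `n_background_other`), `odds_ratio`, `p_value`, `q_value`,
#'   `significant`. Counts sum to the background size.
#' @export
fisher_enrichment <- function(selected, background, annotation,
                              fdr_cutoff = 0.1) {
  selected <- unique(as.character(selected))
  background <- unique(as.character(background))
  if (!all(selected %in% background)) {
    stop("`selected` must be a subset of `background`")
  }
  if (length(selected) == 0) {
    warning("empty selection; no enrichment to test")
    return(tibble::tibble(term = character(0), term_name = character(0),
                          n_selected_term = integer(0),
                          n_selected_other = integer(0),
                          n_background_term = integer(0),
                          n_background_other = integer(0),
                          odds_ratio = numeric(0), p_value = numeric(0),
                          q_value = numeric(0), significant = logical(0)))
  }
  annotation <- tibble::as_tibble(annotation)
  stopifnot(all(c("feature_id", "term") %in% names(annotation)))
  annotation <- annotation[annotation$feature_id %in% background, ]
  term_names <- if ("term_name" %in% names(annotation)) {
    stats::setNames(annotation$term_name, annotation$term)
  } else {
    NULL
  }
  terms <- unique(annotation$term)
  n_bg <- length(background)
  n_sel <- length(selected)
  rows <- purrr::map(terms, function(tm) {
    members <- unique(annotation$feature_id[annotation$term == tm])
    a <- sum(selected %in% members)            # selected, in term
    b <- n_sel - a                              # selected, not in term
    c_ <- length(members) - a                   # unselected, in term
    d <- n_bg - n_sel - c_                      # unselected, not in term
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                             alternative = "two.sided")
    tibble::tibble(term = tm,
                   term_name = if (is.null(term_names)) tm
                               else unname(term_names[tm]),
                   n_selected_term = a, n_selected_other = b,
                   n_background_term = c_, n_background_other = d,
                   odds_ratio = unname(ft$estimate),
                   p_value = ft$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value < fdr_cutoff
  dplyr::arrange(out, .data$q_value, .data$p_value)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: `q_i = min_{j >= i} p_(j) * m / j`
#' over the ranked p-values, mapped back to the input order (so shuffling
#' the input permutes the output identically).
#'
#' @param pvals Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Write an enrichment table as TSV, sorted by q-value
#' @param x Result of [fisher_enrichment()].
#' @param path Output path.
#' @export
write_enrichment <- function(x, path) {
  utils::write.table(dplyr::arrange(x, .data$q_value), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-to-term annotation map
#'
#' Two-column TSV (feature id, term id), optionally with a third column of
#' term display names.
#'
#' @param path Path to the annotation TSV (no header required; a header line
#'   starting with `feature_id` is tolerated).
#' @return Tibble with columns `feature_id`, `term` (and `term_name` when
#'   present).
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (identical(df[1, 1], "feature_id")) df <- df[-1, , drop = FALSE]
  names(df)[1:2] <- c("feature_id", "term")
  if (ncol(df) >= 3) names(df)[3] <- "term_name"
  tibble::as_tibble(df)
}
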