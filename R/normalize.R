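#' Geometric mean of the positive entries of a vector
#'
#' Sequencing abundance vectors contain structural zeros; the per-sample
#' geometric mean used for compositional normalization is taken over the
#' strictly positive entries only, with no pseudocount, which preserves
#' invariance to per-sample rescaling of the counts.
#'
#' @param x Numeric vector of nonnegative values with at least one positive
#'   entry.
#' @return The geometric mean `exp(mean(log(x[x > 0])))`.
#' @export
#' @examples
#' geometric_mean_positive(c(1, 0, 16)) # sqrt(16) = 4
geometric_mean_positive <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("`x` must be nonnegative and finite")
  }
  pos <- x[x > 0]
  if (length(pos) == 0L) {
    stop("all entries are zero: sample has no usable abundances")
  }
  exp(mean(log(pos)))
}

per_sample_geometric_means <- function(values) {
  apply(values, 2L, geometric_mean_positive)
}

#' Modified-RPKM normalization of a gene-family count table
#'
#' Divides each count by the feature length in kilobases and by the sample's
#' geometric mean of counts, adjusting for gene length and for the
#' compositional, library-size-driven scale of each sample in one step. This
#' is a hybrid between RPKM and a centred-log-ratio-style correction, applied
#' without taking logs so zeros stay zeros.
#'
#' @param table A raw [feature_table()] with per-feature `lengths`.
#' @return A [feature_table()] tagged `"modified_rpkm"`.
#' @export
normalize_modified_rpkm <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  lengths <- attr(table, "lengths")
  if (is.null(lengths)) {
    stop("table has no feature lengths; use normalize_geometric_mean() ",
         "for length-free (species) tables")
  }
  g <- per_sample_geometric_means(table)
  vals <- unclass(table) / (lengths / 1000)   # recycles by row
  vals <- sweep(vals, 2L, g, "/")
  restore_feature_table(vals, table, normalization = "modified_rpkm")
}

#' Per-sample geometric-mean normalization (species tables)
#'
#' Divides each sample's abundances by that sample's geometric mean of
#' positive counts; no length adjustment.
#'
#' @param table A raw [feature_table()].
#' @return A [feature_table()] tagged `"geometric_mean_only"`.
#' @export
normalize_geometric_mean <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  g <- per_sample_geometric_means(table)
  vals <- sweep(unclass(table), 2L, g, "/")
  restore_feature_table(vals, table, normalization = "geometric_mean_only")
}

#' Prevalence filter
#'
#' Retains features observed (value > 0) in at least `min_prevalence` of
#' samples; the boundary is inclusive ("at least"). Feature order is
#' preserved. Filtering twice at the same threshold is a no-op.
#'
#' @param table A [feature_table()].
#' @param min_prevalence Fraction in (0, 1]; default 0.10.
#' @return The filtered [feature_table()].
#' @export
prevalence_filter <- function(table, min_prevalence = 0.10) {
  stopifnot(inherits(table, "feature_table"),
            min_prevalence > 0, min_prevalence <= 1)
  prev <- rowMeans(unclass(table) > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) {
    warning("no features pass the prevalence filter")
  }
  restore_feature_table(unclass(table)[keep, , drop = FALSE], table)
}
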