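#' Construct a metagenomic feature table
#'
#' A feature table holds nonnegative abundances of microbial gene families or
#' species, one row per feature and one column per sample. Gene-family tables
#' may carry per-feature lengths (in bases) used by length-aware normalization;
#' species tables have no lengths.
#'
#' @param values Numeric matrix, features x samples, nonnegative and finite.
#'   Row names are feature identifiers, column names are sample identifiers
#'   (both required and unique).
#' @param lengths Optional integer vector of feature lengths in bases, one per
#'   feature (named or in row order). All must be positive.
#' @param normalization Normalization tag; `"raw"` for counts,
#'   `"modified_rpkm"` or `"geometric_mean_only"` after normalization.
#'
#' @return An object of class `feature_table`: the value matrix with
#'   `lengths` and `normalization` attributes.
#' @export
#' @examples
#' m <- matrix(c(0, 5, 2, 7), 2, 2,
#'             dimnames = list(c("K001", "K002"), c("s1", "s2")))
#' ft <- feature_table(m, lengths = c(900L, 1500L))
feature_table <- function(values, lengths = NULL,
                          normalization = c("raw", "modified_rpkm",
                                            "geometric_mean_only")) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) stop("feature ids must be unique")
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  if (any(!is.finite(values))) stop("feature table contains non-finite values")
  if (any(values < 0)) stop("feature table contains negative values")
  if (!is.null(lengths)) {
    if (!is.null(names(lengths))) {
      missing_len <- setdiff(rownames(values), names(lengths))
      if (length(missing_len) > 0) {
        stop("lengths missing for features: ",
             paste(utils::head(missing_len, 5), collapse = ", "))
      }
      lengths <- lengths[rownames(values)]
    } else if (length(lengths) != nrow(values)) {
      stop("`lengths` must have one entry per feature")
    }
    lengths <- as.numeric(lengths)
    if (any(!is.finite(lengths)) || any(lengths <= 0)) {
      stop("all feature lengths must be positive and finite")
    }
    names(lengths) <- rownames(values)
  }
  structure(values,
            lengths = lengths,
            normalization = normalization,
            class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples [%s]%s\n",
              nrow(x), ncol(x), attr(x, "normalization"),
              if (is.null(attr(x, "lengths"))) "" else ", with lengths"))
  nr <- min(nrow(x), 5L)
  nc <- min(ncol(x), 5L)
  print(unclass(x)[seq_len(nr), seq_len(nc), drop = FALSE], ...)
  if (nrow(x) > nr || ncol(x) > nc) cat("...\n")
  invisible(x)
}

feature_ids <- function(x) rownames(x)
sample_ids <- function(x) colnames(x)

# rebuild the class/attributes after a plain-matrix operation
restore_feature_table <- function(values, template, normalization = NULL) {
  lens <- attr(template, "lengths")
  if (!is.null(lens)) lens <- lens[rownames(values)]
  feature_table(values, lengths = lens,
                normalization = normalization %||%
                  attr(template, "normalization"))
}

#' Read a feature table from a tab-separated file
#'
#' The file has feature identifiers in the first column and a header row of
#' sample identifiers. Comment lines starting with `#` are ignored. An
#' optional two-column lengths file (feature id, length in bp) attaches
#' per-feature lengths.
#'
#' @param path Path to the TSV abundance table.
#' @param lengths_path Optional path to a two-column TSV of feature lengths.
#' @param normalization Tag recorded on the returned table (default `"raw"`).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, lengths_path = NULL,
                               normalization = "raw") {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  lengths <- NULL
  if (!is.null(lengths_path)) {
    ldf <- utils::read.delim(lengths_path, header = FALSE,
                             comment.char = "#",
                             stringsAsFactors = FALSE)
    lengths <- stats::setNames(as.numeric(ldf[[2]]), as.character(ldf[[1]]))
  }
  feature_table(m, lengths = lengths, normalization = normalization)
}

#' Write a feature table as TSV
#'
#' Writes the same dialect [read_feature_table()] reads, preceded by a comment
#' header recording the normalization tag.
#'
#' @param x A [feature_table()].
#' @param path Output path.
#' @param extra_comments Optional character vector of additional `#` header
#'   lines (e.g. the prevalence threshold applied).
#' @export
write_feature_table <- function(x, path, extra_comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# normalization: %s", attr(x, "normalization")), con)
  if (!is.null(extra_comments)) {
    writeLines(paste0("# ", extra_comments), con)
  }
  writeLines(paste(c("feature_id", colnames(x)), collapse = "\t"), con)
  utils::write.table(data.frame(feature_id = rownames(x),
                                unclass(x), check.names = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
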