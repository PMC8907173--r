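#' Validate a covariate table
#'
#' Checks the sample covariates used by residualization: one row per sample,
#' no missing values, at most two members per family (twin pairs), zygosity
#' labels in {MZ, DZ} (singletons may carry either). Ancestry PC columns are
#' any columns named `PC1`, `PC2`, ...
#'
#' @param cov Data frame with columns `sample_id`, `age`, `bmi`, `shipment`,
#'   `family_id`, `zygosity`, and optional `PC*` columns.
#' @return The validated covariate table as a tibble.
#' @export
validate_covariates <- function(cov) {
  cov <- tibble::as_tibble(cov)
  needed <- c("sample_id", "age", "bmi", "shipment", "family_id", "zygosity")
  missing_cols <- setdiff(needed, names(cov))
  if (length(missing_cols) > 0) {
    stop("covariate table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(cov$sample_id)) stop("duplicate sample_id")
  if (anyNA(cov[needed])) stop("missing values in covariates")
  fam_sizes <- table(cov$family_id)
  if (any(fam_sizes > 2)) stop("family_id groups must have at most 2 members")
  if (!all(cov$zygosity %in% c("MZ", "DZ"))) {
    stop("zygosity must be 'MZ' or 'DZ'")
  }
  cov
}

pc_columns <- function(cov) {
  grep("^PC[0-9]+$", names(cov), value = TRUE)
}

#' Build the fixed-effect design matrix
#'
#' Intercept, age, BMI, shipment-batch dummies (reference coded; omitted if
#' only one batch is present) and any ancestry PC columns, in a stable column
#' order. Constant covariate columns are kept (rank issues are the fitter's
#' concern) with a warning.
#'
#' @param cov A validated covariate table (see [validate_covariates()]).
#' @return Numeric design matrix, samples x columns, with row names from
#'   `sample_id`.
#' @export
build_design <- function(cov) {
  cov <- validate_covariates(cov)
  X <- cbind(`(Intercept)` = 1, age = cov$age, bmi = cov$bmi)
  ship <- factor(cov$shipment)
  if (nlevels(ship) > 1L) {
    dummies <- stats::model.matrix(~ship)[, -1L, drop = FALSE]
    colnames(dummies) <- paste0("shipment", levels(ship)[-1L])
    X <- cbind(X, dummies)
  }
  pcs <- pc_columns(cov)
  if (length(pcs) > 0) {
    X <- cbind(X, as.matrix(cov[pcs]))
  }
  if (stats::sd(cov$age) == 0) warning("age is constant across samples")
  if (stats::sd(cov$bmi) == 0) warning("bmi is constant across samples")
  rownames(X) <- cov$sample_id
  X
}

#' Read a covariate table from TSV
#' @param path Path to a tab-separated covariate file with a header.
#' @return A validated tibble.
#' @export
read_covariates <- function(path) {
  validate_covariates(utils::read.delim(path, header = TRUE,
                                        comment.char = "#",
                                        stringsAsFactors = FALSE))
}
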