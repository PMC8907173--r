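#' Construct a genotype matrix
#'
#' Holds bi-allelic genotype calls as minor-allele counts (0, 1, 2, or `NA`
#' for missing), one row per sample and one column per locus, together with
#' per-locus metadata. Loci must be ordered by nondecreasing position within
#' chromosome (required by windowed LD pruning).
#'
#' @param calls Numeric matrix, samples x loci, entries in {0, 1, 2, NA}.
#'   Row names are sample ids; column names are locus ids.
#' @param loci Optional data frame of locus metadata with columns `id`,
#'   `chrom`, `pos` (and optionally `ref`, `alt`); defaults to a single
#'   chromosome with positions in column order.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(calls, loci = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  if (is.null(colnames(calls))) {
    colnames(calls) <- paste0("snp", seq_len(ncol(calls)))
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("sample", seq_len(nrow(calls)))
  }
  bad <- !(calls %in% c(0, 1, 2)) & !is.na(calls)
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  if (is.null(loci)) {
    loci <- tibble::tibble(id = colnames(calls), chrom = "1",
                           pos = seq_len(ncol(calls)))
  } else {
    loci <- tibble::as_tibble(loci)
    stopifnot(all(c("id", "chrom", "pos") %in% names(loci)))
    loci <- loci[match(colnames(calls), loci$id), ]
    if (anyNA(loci$id)) stop("loci metadata missing for some call columns")
    unsorted <- loci |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(ok = !is.unsorted(.data$pos)) |>
      dplyr::pull(.data$ok)
    if (!all(unsorted)) {
      stop("locus positions must be nondecreasing within chromosome")
    }
  }
  structure(calls, loci = loci,
            class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d loci (%d missing calls)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

loci_meta <- function(g) attr(g, "loci")

subset_loci <- function(g, keep) {
  genotype_matrix(unclass(g)[, keep, drop = FALSE],
                  loci = loci_meta(g)[keep, , drop = FALSE])
}

#' Drop loci with any missing call
#'
#' The strictest missingness filter (plink's `--geno 0`): a locus with even a
#' single missing genotype is removed.
#'
#' @param g A [genotype_matrix()].
#' @return The filtered [genotype_matrix()].
#' @export
filter_geno_missing <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  keep <- colSums(is.na(unclass(g))) == 0L
  subset_loci(g, keep)
}

minor_allele_freq <- function(calls) {
  f <- colMeans(calls) / 2
  pmin(f, 1 - f)
}

#' Drop loci with low minor allele frequency
#'
#' Keeps loci whose minor allele frequency `min(f, 1 - f)`, with
#' `f = sum(calls) / (2n)`, is at least `min_maf` (boundary inclusive).
#' Requires complete calls; run [filter_geno_missing()] first.
#'
#' @param g A [genotype_matrix()] with no missing calls.
#' @param min_maf Minimum minor allele frequency; default 0.10.
#' @return The filtered [genotype_matrix()].
#' @export
filter_geno_maf <- function(g, min_maf = 0.10) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g)) stop("missing calls present; run filter_geno_missing() first")
  subset_loci(g, minor_allele_freq(unclass(g)) >= min_maf)
}

#' Hardy-Weinberg equilibrium chi-square for one locus
#'
#' 1-df goodness-of-fit statistic comparing observed genotype counts
#' (`n0`, `n1`, `n2` copies of the minor allele) with the Hardy-Weinberg
#' expectations `n(1-f)^2, 2nf(1-f), nf^2` computed from the sample allele
#' frequency.
#'
#' @param n0,n1,n2 Genotype counts.
#' @return A list with `statistic` and `p.value`. Monomorphic loci (expected
#'   counts of zero) return `statistic = Inf`, `p.value = 0`.
#' @export
hwe_chisq <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  f <- (n1 + 2 * n2) / (2 * n)
  e <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
  if (any(e == 0)) {
    return(list(statistic = Inf, p.value = 0))
  }
  stat <- sum((c(n0, n1, n2) - e)^2 / e)
  list(statistic = stat, p.value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE))
}

#' Drop loci violating Hardy-Weinberg equilibrium
#'
#' Applies the 1-df chi-square test of [hwe_chisq()] per locus and removes
#' loci with `p < alpha`. Monomorphic loci (zero expected heterozygotes)
#' cannot be tested and are dropped with a warning.
#'
#' @param g A [genotype_matrix()] with no missing calls.
#' @param alpha Rejection level; default 0.001 (plink `--hwe 0.001`).
#' @return The filtered [genotype_matrix()].
#' @export
filter_geno_hwe <- function(g, alpha = 0.001) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g)) stop("missing calls present; run filter_geno_missing() first")
  calls <- unclass(g)
  n0 <- colSums(calls == 0)
  n1 <- colSums(calls == 1)
  n2 <- colSums(calls == 2)
  pvals <- vapply(seq_len(ncol(calls)),
                  function(j) hwe_chisq(n0[j], n1[j], n2[j])$p.value,
                  numeric(1))
  mono <- (n1 + n2) == 0L | (n0 + n1) == 0L
  if (any(mono)) {
    warning(sum(mono), " monomorphic loci dropped (HWE untestable)")
  }
  subset_loci(g, pvals >= alpha)
}

#' Prune loci in high linkage disequilibrium
#'
#' Windowed LD pruning in the style of plink's `--indep-pairwise`: within a
#' sliding window of `window` loci advancing by `step` (within chromosome),
#' while any surviving pair has squared Pearson correlation of allele counts
#' exceeding `r2_max`, the member with the lower minor allele frequency is
#' removed (tie: the later position). Passes repeat until no within-window
#' pair remains above the threshold, so the result is deterministic and
#' satisfies an exhaustive pair check.
#'
#' @param g A [genotype_matrix()] with no missing calls, ordered by position.
#' @param window Window size in loci; default 50.
#' @param step Window advance in loci; default 10.
#' @param r2_max Maximum allowed squared correlation; default 0.8.
#' @return The pruned [genotype_matrix()].
#' @export
ld_prune <- function(g, window = 50, step = 10, r2_max = 0.8) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g)) stop("missing calls present; run filter_geno_missing() first")
  calls <- unclass(g)
  loci <- loci_meta(g)
  maf <- minor_allele_freq(calls)
  alive <- rep(TRUE, ncol(calls))
  for (chr in unique(loci$chrom)) {
    idx_chr <- which(loci$chrom == chr)
    repeat {
      removed_any <- FALSE
      cur <- idx_chr[alive[idx_chr]]
      if (length(cur) < 2L) break
      starts <- seq(1L, max(1L, length(cur) - 1L), by = step)
      for (s in starts) {
        win <- cur[s:min(s + window - 1L, length(cur))]
        win <- win[alive[win]]
        if (length(win) < 2L) next
        repeat {
          wcall <- calls[, win, drop = FALSE]
          r2 <- suppressWarnings(stats::cor(wcall))^2
          r2[!is.finite(r2)] <- 0
          diag(r2) <- 0
          if (max(r2) <= r2_max) break
          hit <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
          a <- win[hit[1L]]; b <- win[hit[2L]]
          # drop the lower-MAF member; tie -> later position
          drop_i <- if (maf[a] < maf[b]) a
                    else if (maf[b] < maf[a]) b
                    else if (loci$pos[a] >= loci$pos[b]) a else b
          alive[drop_i] <- FALSE
          removed_any <- TRUE
          win <- win[win != drop_i]
          if (length(win) < 2L) break
        }
      }
      if (!removed_any) break
    }
  }
  subset_loci(g, alive)
}

#' Code genotypes for additive and dominance effects
#'
#' Each locus expands to two columns: the additive component takes values
#' {1, 0, -1} for 0, 1, 2 copies of the minor allele, and the dominance
#' component takes {-1, 1, -1}, so that on a genotype-balanced sample
#' (frequencies 1/4, 1/2, 1/4) the two columns are exactly orthogonal. The
#' two columns of a locus form one selection group for the group lasso.
#'
#' @param g A [genotype_matrix()] with no missing calls.
#' @return A `coded_genotypes` object: matrix samples x (2 * n_loci) with a
#'   `groups` attribute (character vector mapping each column to its locus).
#' @export
code_additive_dominance <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- unclass(g)
  if (anyNA(calls)) stop("missing calls present; filter loci first")
  add <- 1 - calls                  # 0,1,2 -> 1,0,-1
  dom <- 1 - 2 * abs(1 - calls)     # 0,1,2 -> -1,1,-1
  loci <- colnames(calls)
  out <- matrix(0, nrow(calls), 2L * ncol(calls))
  out[, seq(1L, ncol(out), by = 2L)] <- add
  out[, seq(2L, ncol(out), by = 2L)] <- dom
  colnames(out) <- as.vector(rbind(paste0(loci, "_add"),
                                   paste0(loci, "_dom")))
  rownames(out) <- rownames(calls)
  groups <- rep(loci, each = 2L)
  names(groups) <- colnames(out)
  structure(out, groups = groups,
            class = c("coded_genotypes", "matrix", "array"))
}

#' @export
print.coded_genotypes <- function(x, ...) {
  cat(sprintf("<coded_genotypes> %d samples x %d columns (%d loci)\n",
              nrow(x), ncol(x), length(unique(attr(x, "groups")))))
  invisible(x)
}

#' Decode an additive/dominance coded matrix back to calls
#'
#' Inverse of [code_additive_dominance()]; used to verify the coding is
#' lossless.
#'
#' @param coded A `coded_genotypes` object.
#' @return A plain matrix of calls in {0, 1, 2}.
#' @export
decode_additive_dominance <- function(coded) {
  add <- unclass(coded)[, seq(1L, ncol(coded), by = 2L), drop = FALSE]
  calls <- 1 - add
  colnames(calls) <- unique(attr(coded, "groups"))
  calls
}

#' Write a coded genotype matrix and its group map as TSV
#'
#' The coded matrix is written samples x columns with a `sample_id` first
#' column; the group map is a two-column file (column id, locus id) that
#' lets the group-lasso structure be reconstructed.
#'
#' @param coded A `coded_genotypes` object.
#' @param path Output path for the coded matrix.
#' @param group_path Output path for the column-to-locus map.
#' @export
write_coded_genotypes <- function(coded, path, group_path) {
  utils::write.table(data.frame(sample_id = rownames(coded),
                                unclass(coded), check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  groups <- attr(coded, "groups")
  utils::write.table(data.frame(column = names(groups),
                                locus = unname(groups)),
                     group_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Ancestry principal components robust to twin structure
#'
#' Centers and scales the allele-count matrix, fits PCA loadings on one
#' representative per family (the lowest-sorting sample id, so that
#' duplicated co-twin genotypes do not distort the eigenstructure), then
#' scores all samples — including held-out co-twins — on those loadings.
#'
#' @param g A filtered, complete [genotype_matrix()].
#' @param k Number of components; `k = 0` yields an `n x 0` matrix.
#' @param family_ids Vector of family labels, one per sample (row of `g`).
#' @return Matrix of PC scores, samples x `k`.
#' @export
ancestry_pcs <- function(g, k = 10, family_ids = rownames(g)) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- unclass(g)
  if (anyNA(calls)) stop("missing calls present; filter loci first")
  if (k > ncol(calls)) stop("k exceeds the number of retained loci")
  if (k == 0L) {
    return(matrix(0, nrow(calls), 0L, dimnames = list(rownames(calls), NULL)))
  }
  fam <- as.character(rep_len(family_ids, nrow(calls)))
  reps <- vapply(split(rownames(calls), fam),
                 function(ids) sort(ids)[1L], character(1))
  ctr <- colMeans(calls[reps, , drop = FALSE])
  scl <- apply(calls[reps, , drop = FALSE], 2L, stats::sd)
  scl[scl == 0] <- 1
  std_all <- sweep(sweep(calls, 2L, ctr), 2L, scl, "/")
  pc <- stats::prcomp(std_all[reps, , drop = FALSE],
                      center = FALSE, scale. = FALSE)
  k_eff <- min(k, ncol(pc$rotation))
  scores <- std_all %*% pc$rotation[, seq_len(k_eff), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k_eff))
  scores
}
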