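# Twin-cohort simulator. Genotypes are built from explicit haplotypes: a
# Gaussian-copula latent variable with equicorrelation inside LD blocks
# gives each haplotype its alleles (marginal frequency exact, Hardy-Weinberg
# exact because the two haplotypes of a founder are independent). MZ twins
# duplicate one simulated genotype; DZ twins inherit one haplotype per
# parent per block, giving the expected 1/2 identity-by-descent. Abundances
# are Tweedie compound Poisson-gamma draws whose log-means carry a planted
# latent factor (a standardized sum of planted SNP dosages), covariate
# effects, and a per-family intercept, so every downstream module can be
# validated against known truth.

#' Configuration for a synthetic twin cohort
#'
#' Defaults describe the reference cohort used throughout the package's
#' validation: 150 twin pairs (28% monozygotic), 2,000 loci in LD blocks of
#' 10, 1,000 microbial features with Tweedie power 1.6 and dispersion 2, five
#' planted SNPs driving twenty planted features through a shared latent
#' factor with effect 0.5 on the log-mean scale.
#'
#' @param n_pairs Number of twin pairs.
#' @param mz_fraction Fraction of pairs that are monozygotic.
#' @param n_loci Number of loci.
#' @param maf_range Range of per-locus minor allele frequencies.
#' @param ld_block_size Loci per LD block.
#' @param ld_rho Latent within-block equicorrelation (controls LD strength).
#' @param n_features Number of microbial features.
#' @param tweedie_p,tweedie_phi Tweedie power (in (1,2)) and dispersion.
#' @param n_planted_snps,n_planted_features Sizes of the planted sets.
#' @param effect_size Latent-factor effect on planted features' log-means.
#' @param latent_noise_sd Non-genetic noise added to the latent factor.
#' @param planted_maf_range MAF range for planted loci (common variants).
#' @param age_effect,bmi_effect Log-mean effects per centered unit.
#' @param n_shipments,shipment_sd Number of shipment batches and the SD of
#'   their log-mean offsets.
#' @param family_sd SD of the per-feature, per-family random intercept.
#' @param length_range Gene length range in bases.
#' @param base_logmean_mean,base_logmean_sd Distribution of feature baseline
#'   log-means.
#' @param n_terms Number of annotation terms (planted features concentrate
#'   in the first two).
#' @param seed Integer seed; identical config and seed give an identical
#'   cohort.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_pairs = 150L, mz_fraction = 0.28,
                              n_loci = 2000L, maf_range = c(0.05, 0.5),
                              ld_block_size = 10L, ld_rho = 0.95,
                              n_features = 1000L, tweedie_p = 1.6,
                              tweedie_phi = 2,
                              n_planted_snps = 5L,
                              n_planted_features = 20L,
                              effect_size = 0.5, latent_noise_sd = 0.3,
                              planted_maf_range = c(0.2, 0.45),
                              age_effect = 0.01, bmi_effect = 0.02,
                              n_shipments = 3L, shipment_sd = 0.2,
                              family_sd = 0.3,
                              length_range = c(300L, 3000L),
                              base_logmean_mean = 1, base_logmean_sd = 1,
                              n_terms = 50L, seed = 20220309L) {
  cfg <- as.list(environment())
  stopifnot(n_pairs > 0, n_loci > 0, n_features > 0,
            tweedie_p > 1, tweedie_p < 2, tweedie_phi > 0,
            mz_fraction >= 0, mz_fraction <= 1,
            n_planted_snps <= n_loci, n_planted_features <= n_features,
            effect_size >= 0)
  structure(cfg, class = "simulation_config")
}

# haplotypes with block-equicorrelated Gaussian copula; rows = haplotypes
sim_haplotypes <- function(n_hap, maf, block_id, rho) {
  n_loci <- length(maf)
  z <- matrix(stats::rnorm(n_hap * n_loci), n_hap, n_loci)
  for (b in unique(block_id)) {
    cols <- which(block_id == b)
    shared <- stats::rnorm(n_hap)
    z[, cols] <- sqrt(rho) * shared + sqrt(1 - rho) * z[, cols]
  }
  thr <- stats::qnorm(maf)
  t(t(z) < thr) * 1
}

#' Simulate twin-structured genotypes
#'
#' See the file-level notes: copula haplotypes with LD blocks, exact HWE for
#' founders, duplicated MZ rows, DZ rows from shared parental haplotypes
#' (expected IBD 1/2 per block). Planted loci are placed at the head of
#' evenly spaced blocks with common-variant MAFs.
#'
#' @param config A [simulation_config()].
#' @return A [genotype_matrix()] with attributes `planted_snps` (locus ids),
#'   `pair_info` (tibble: family_id, zygosity) and `maf` (the generating
#'   frequencies). Randomness uses the current RNG state; see
#'   [simulate_cohort()] for the seeded entry point.
#' @export
simulate_genotypes <- function(config) {
  n_loci <- config$n_loci
  block_id <- rep(seq_len(ceiling(n_loci / config$ld_block_size)),
                  each = config$ld_block_size)[seq_len(n_loci)]
  maf <- stats::runif(n_loci, config$maf_range[1], config$maf_range[2])
  n_blocks <- max(block_id)
  planted_blocks <- unique(round(seq(1, n_blocks,
                                     length.out = config$n_planted_snps)))
  planted_idx <- vapply(planted_blocks[seq_len(config$n_planted_snps)],
                        function(b) which(block_id == b)[1L], integer(1))
  maf[planted_idx] <- stats::runif(length(planted_idx),
                                   config$planted_maf_range[1],
                                   config$planted_maf_range[2])
  n_pairs <- config$n_pairs
  n_mz <- round(config$mz_fraction * n_pairs)
  zygosity <- c(rep("MZ", n_mz), rep("DZ", n_pairs - n_mz))
  fam_ids <- sprintf("F%03d", seq_len(n_pairs))
  calls <- matrix(0, 2L * n_pairs, n_loci)
  row <- 0L
  for (pi in seq_len(n_pairs)) {
    if (zygosity[pi] == "MZ") {
      h <- sim_haplotypes(2L, maf, block_id, config$ld_rho)
      g <- h[1L, ] + h[2L, ]
      calls[row + 1L, ] <- g
      calls[row + 2L, ] <- g
    } else {
      hp <- sim_haplotypes(4L, maf, block_id, config$ld_rho) # 2 parents
      for (child in 1:2) {
        pick1 <- stats::rbinom(n_blocks, 1L, 0.5) + 1L       # from parent 1
        pick2 <- stats::rbinom(n_blocks, 1L, 0.5) + 3L       # from parent 2
        calls[row + child, ] <- hp[cbind(pick1[block_id],
                                         seq_len(n_loci))] +
          hp[cbind(pick2[block_id], seq_len(n_loci))]
      }
    }
    row <- row + 2L
  }
  sample_ids <- as.vector(t(outer(fam_ids, 1:2, paste, sep = "_")))
  dimnames(calls) <- list(sample_ids,
                          sprintf("snp%05d", seq_len(n_loci)))
  g <- genotype_matrix(calls,
                       loci = tibble::tibble(
                         id = colnames(calls), chrom = "1",
                         pos = seq_len(n_loci)))
  attr(g, "planted_snps") <- colnames(calls)[planted_idx]
  attr(g, "pair_info") <- tibble::tibble(family_id = fam_ids,
                                         zygosity = zygosity)
  attr(g, "maf") <- maf
  g
}

simulate_covariates <- function(config, pair_info) {
  n_pairs <- nrow(pair_info)
  age_fam <- stats::runif(n_pairs, 40, 70)   # twins share age
  tibble::tibble(
    sample_id = as.vector(t(outer(pair_info$family_id, 1:2,
                                  paste, sep = "_"))),
    age = rep(age_fam, each = 2L),
    bmi = stats::rnorm(2L * n_pairs, 26, 4),
    shipment = paste0("batch",
                      sample.int(config$n_shipments, 2L * n_pairs,
                                 replace = TRUE)),
    family_id = rep(pair_info$family_id, each = 2L),
    zygosity = rep(pair_info$zygosity, each = 2L))
}

#' Simulate a complete twin cohort with planted associations
#'
#' Generates genotypes, covariates, raw Tweedie-distributed gene-family
#' counts and a feature-to-term annotation map under a single seeded RNG
#' stream. The latent factor per sample is the standardized sum of planted
#' SNP dosages plus Gaussian noise; planted features receive
#' `effect_size * u` on the log-mean; all features receive the covariate
#' terms and a per-family intercept; counts scale with gene length so the
#' modified-RPKM normalization is exercised end to end.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort` list: `genotypes`, `abundances` (raw
#'   [feature_table()] with lengths), `covariates`, `annotation`, and
#'   `truth` (planted locus/feature ids, the latent factor, the config).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(config$seed, {
    g <- simulate_genotypes(config)
    pair_info <- attr(g, "pair_info")
    cov <- simulate_covariates(config, pair_info)
    n <- nrow(g)
    planted_snps <- attr(g, "planted_snps")
    dos <- rowSums(unclass(g)[, planted_snps, drop = FALSE])
    u <- drop(scale(dos)) + config$latent_noise_sd * stats::rnorm(n)
    u <- drop(scale(u))
    nf <- config$n_features
    planted_features <- sort(sample.int(nf, config$n_planted_features))
    feature_ids <- sprintf("K%05d", seq_len(nf))
    lengths <- round(stats::runif(nf, config$length_range[1],
                                  config$length_range[2]))
    base <- stats::rnorm(nf, config$base_logmean_mean,
                         config$base_logmean_sd)
    ship_eff <- stats::rnorm(config$n_shipments, 0, config$shipment_sd)
    names(ship_eff) <- paste0("batch", seq_len(config$n_shipments))
    fam_int <- matrix(stats::rnorm(nf * nrow(pair_info), 0,
                                   config$family_sd),
                      nf, nrow(pair_info),
                      dimnames = list(NULL, pair_info$family_id))
    cov_term <- config$age_effect * (cov$age - mean(cov$age)) +
      config$bmi_effect * (cov$bmi - mean(cov$bmi)) +
      ship_eff[cov$shipment]
    eta <- matrix(base, nf, n) +
      config$effect_size *
        (as.numeric(seq_len(nf) %in% planted_features) %o% u) +
      matrix(cov_term, nf, n, byrow = TRUE) +
      fam_int[, cov$family_id]
    mu <- exp(eta) * (lengths / 1000)
    counts <- matrix(sample_tweedie(length(mu), as.vector(mu),
                                    config$tweedie_phi, config$tweedie_p),
                     nf, n)
    dimnames(counts) <- list(feature_ids, cov$sample_id)
    abund <- feature_table(counts,
                           lengths = stats::setNames(lengths, feature_ids))
    terms <- sprintf("T%02d", seq_len(config$n_terms))
    term_of <- terms[sample.int(max(config$n_terms - 2L, 1L), nf,
                                replace = TRUE) + 2L]
    term_of[planted_features] <- terms[1:2][
      (seq_along(planted_features) %% 2L) + 1L]
    annotation <- tibble::tibble(feature_id = feature_ids, term = term_of)
    structure(list(genotypes = g, abundances = abund, covariates = cov,
                   annotation = annotation,
                   truth = list(planted_snps = planted_snps,
                                planted_features =
                                  feature_ids[planted_features],
                                latent = stats::setNames(u, cov$sample_id),
                                config = config)),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(paste0("<synthetic_cohort> %d samples (%d pairs), %d loci, ",
                     "%d features\n  planted: %d SNPs -> %d features, ",
                     "effect %.2f, Tweedie p = %.2f, phi = %.2f\n"),
              nrow(x$genotypes), cfg$n_pairs, ncol(x$genotypes),
              nrow(x$abundances), length(x$truth$planted_snps),
              length(x$truth$planted_features), cfg$effect_size,
              cfg$tweedie_p, cfg$tweedie_phi))
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's file dialects
#'
#' Counts and covariates as TSV, genotypes as a TSV dosage matrix, lengths
#' and annotation as two-column TSVs, truth as JSON — the same formats the
#' real-data path reads, so fixtures and real inputs are interchangeable.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(cohort$abundances, file.path(dir, "abundances.tsv"))
  utils::write.table(
    data.frame(feature_id = rownames(cohort$abundances),
               length = attr(cohort$abundances, "lengths")),
    file.path(dir, "lengths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  gm <- unclass(cohort$genotypes)
  utils::write.table(
    data.frame(sample_id = rownames(gm), gm, check.names = FALSE),
    file.path(dir, "genotypes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(planted_snps = cohort$truth$planted_snps,
         planted_features = cohort$truth$planted_features,
         latent = unname(cohort$truth$latent),
         seed = cohort$truth$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a TSV dosage matrix as a genotype matrix
#'
#' Rows are samples (first column `sample_id`), columns are locus ids,
#' entries 0/1/2/NA.
#'
#' @param path Path to the TSV file.
#' @return A [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  genotype_matrix(m)
}

#' Read genotypes from a VCF file
#'
#' Takes the GT field of a (plain or bgzipped) VCF and counts ALT alleles
#' per sample. Multi-allelic sites are dropped with a warning. Because the
#' downstream MAF filter and coding are symmetric in allele orientation,
#' ALT-allele counts serve directly as the call matrix.
#'
#' @param path Path to the VCF.
#' @return A [genotype_matrix()] (samples x loci) with locus metadata from
#'   CHROM/POS/ID.
#' @export
read_genotype_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic sites dropped")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  clean <- gsub("|", "/", as.vector(gt), fixed = TRUE)
  vals <- rep(NA_real_, length(clean))
  vals[clean == "0/0"] <- 0
  vals[clean %in% c("0/1", "1/0")] <- 1
  vals[clean == "1/1"] <- 2
  conv <- matrix(vals, nrow(gt), ncol(gt))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) |
                                                         ids == "."]
  calls <- t(conv)
  dimnames(calls) <- list(colnames(gt), ids)
  genotype_matrix(calls,
                  loci = tibble::tibble(id = ids, chrom = fix[, "CHROM"],
                                        pos = as.numeric(fix[, "POS"])))
}
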