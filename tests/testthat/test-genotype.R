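make_geno <- function(calls) {
  genotype_matrix(calls)
}

test_that("missingness filter drops any locus with a missing call", {
  set.seed(21)
  calls <- matrix(rbinom(240 * 20, 2, 0.3), 240, 20)
  calls[5, 3] <- NA                       # one missing call among 240
  g <- make_geno(calls)
  kept <- filter_geno_missing(g)
  expect_equal(ncol(kept), 19)
  expect_false(colnames(g)[3] %in% colnames(kept))
  # random missingness mask vs brute-force scan
  calls2 <- matrix(rbinom(50 * 40, 2, 0.4), 50, 40)
  mask <- matrix(rbinom(50 * 40, 1, 0.02) == 1, 50, 40)
  calls2[mask] <- NA
  g2 <- make_geno(calls2)
  brute <- which(colSums(is.na(calls2)) == 0)
  expect_identical(colnames(filter_geno_missing(g2)),
                   colnames(g2)[brute])
})

test_that("MAF filter uses min(f, 1-f) with an inclusive boundary", {
  # n = 10 samples, calls sum 2 -> f = 0.1 -> retained at 0.10
  calls <- cbind(boundary = c(1, 1, rep(0, 8)),
                 mono = rep(0, 10),
                 common = rep(1, 10))
  g <- make_geno(calls)
  kept <- filter_geno_maf(g, 0.10)
  expect_true("boundary" %in% colnames(kept))
  expect_false("mono" %in% colnames(kept))
  # high-frequency coding: f = 1 -> MAF 0 -> dropped
  calls2 <- cbind(allhom = rep(2, 10), het = rep(1, 10))
  expect_identical(colnames(filter_geno_maf(make_geno(calls2), 0.10)),
                   "het")
  # random matrix vs brute-force allele count
  set.seed(22)
  calls3 <- matrix(rbinom(60 * 50, 2, runif(50, 0.02, 0.5)[
    rep(1:50, each = 60)]), 60, 50)
  g3 <- make_geno(calls3)
  f <- colSums(calls3) / (2 * 60)
  brute <- pmin(f, 1 - f) >= 0.1
  expect_identical(colnames(filter_geno_maf(g3, 0.1)),
                   colnames(g3)[brute])
})

test_that("HWE chi-square matches hand computation", {
  perfect <- hwe_chisq(25, 50, 25)
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p.value, 1)
  # all homozygotes, no hets: expected (25, 50, 25) -> chi2 = 100
  extreme <- hwe_chisq(50, 0, 50)
  expect_equal(extreme$statistic, 100)
  expect_lt(extreme$p.value, 1e-20)
})

test_that("HWE filter drops violating and monomorphic loci", {
  calls <- cbind(ok = rep(c(0, 1, 2, 1), 25),
                 viol = rep(c(0, 2), 50),
                 mono = rep(0, 100))
  g <- make_geno(calls)
  expect_warning(kept <- filter_geno_hwe(g, 0.001), "monomorphic")
  expect_identical(colnames(kept), "ok")
})

test_that("HWE test has the nominal type-I rate on equilibrium loci", {
  set.seed(23)
  n <- 500
  rejections <- vapply(seq_len(4000), function(i) {
    f <- runif(1, 0.1, 0.5)
    calls <- rbinom(n, 2, f)
    n0 <- sum(calls == 0); n1 <- sum(calls == 1); n2 <- sum(calls == 2)
    hwe_chisq(n0, n1, n2)$p.value < 0.001
  }, logical(1))
  # expected 0.1%; allow 3 binomial sigma (plus chi-square approximation slack)
  expect_lt(mean(rejections), 0.001 + 3 * sqrt(0.001 * 0.999 / 4000) + 0.002)
})

test_that("LD pruning removes duplicates and leaves independent loci alone", {
  set.seed(24)
  calls <- matrix(rbinom(100 * 20, 2, 0.4), 100, 20)
  calls[, 7] <- calls[, 3]               # duplicated locus, r2 = 1
  g <- make_geno(calls)
  pruned <- ld_prune(g)
  expect_equal(ncol(pruned), 19)
  expect_true(xor("snp3" %in% colnames(pruned),
                  "snp7" %in% colnames(pruned)))
  # independent loci: nothing removed
  calls2 <- matrix(rbinom(200 * 30, 2, 0.3), 200, 30)
  expect_equal(ncol(ld_prune(make_geno(calls2))), 30)
})

test_that("LD pruning satisfies the exhaustive within-window pair check", {
  set.seed(25)
  n <- 150
  base <- rbinom(n, 2, 0.4)
  calls <- matrix(rbinom(n * 60, 2, 0.35), n, 60)
  # planted correlated block: loci 20..30 are noisy copies of `base`
  for (j in 20:30) {
    flip <- rbinom(n, 1, 0.05)
    calls[, j] <- ifelse(flip == 1, rbinom(n, 2, 0.4), base)
  }
  g <- make_geno(calls)
  pruned <- ld_prune(g, window = 50, step = 10, r2_max = 0.8)
  kept <- unclass(pruned)
  # brute force: every surviving pair within every window obeys r2 <= 0.8
  m <- ncol(kept)
  for (s in seq(1, max(1, m - 1), by = 10)) {
    win <- s:min(s + 49, m)
    if (length(win) < 2) next
    r2 <- suppressWarnings(cor(kept[, win]))^2
    diag(r2) <- 0
    expect_lte(max(r2, na.rm = TRUE), 0.8)
  }
})

test_that("additive/dominance coding matches the published scheme", {
  calls <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "rs1"))
  coded <- code_additive_dominance(make_geno(calls))
  expect_equal(unname(unclass(coded)[, "rs1_add"]), c(1, 0, -1))
  expect_equal(unname(unclass(coded)[, "rs1_dom"]), c(-1, 1, -1))
  expect_equal(unname(attr(coded, "groups")), c("rs1", "rs1"))
})

test_that("coding is orthogonal on balanced genotypes and decodes losslessly", {
  # genotype counts 1:2:1 -> additive and dominance inner product zero
  calls <- matrix(c(0, 1, 1, 2), 4, 1, dimnames = list(NULL, "rs1"))
  coded <- code_additive_dominance(make_geno(calls))
  expect_equal(sum(unclass(coded)[, 1] * unclass(coded)[, 2]), 0)
  # random calls: per-entry lookup oracle + decode roundtrip
  set.seed(26)
  calls2 <- matrix(sample(0:2, 200, replace = TRUE), 20, 10)
  g2 <- make_geno(calls2)
  coded2 <- code_additive_dominance(g2)
  lookup_add <- c(`0` = 1, `1` = 0, `2` = -1)
  lookup_dom <- c(`0` = -1, `1` = 1, `2` = -1)
  for (j in 1:10) {
    expect_equal(unname(unclass(coded2)[, 2 * j - 1]),
                 unname(lookup_add[as.character(calls2[, j])]))
    expect_equal(unname(unclass(coded2)[, 2 * j]),
                 unname(lookup_dom[as.character(calls2[, j])]))
  }
  expect_equal(unname(decode_additive_dominance(coded2)),
               unname(calls2))
  calls2[1, 1] <- NA
  expect_error(code_additive_dominance(make_geno(calls2)), "missing")
})

test_that("genotype filters are idempotent", {
  set.seed(27)
  calls <- matrix(rbinom(120 * 80, 2, runif(80, 0.05, 0.5)[
    rep(1:80, each = 120)]), 120, 80)
  g <- make_geno(calls)
  g1 <- ld_prune(filter_geno_hwe(filter_geno_maf(filter_geno_missing(g))))
  expect_identical(colnames(filter_geno_maf(g1)), colnames(g1))
  expect_identical(colnames(filter_geno_hwe(g1)), colnames(g1))
  expect_identical(colnames(ld_prune(g1)), colnames(g1))
})

test_that("coded genotypes and group map round-trip through TSV", {
  set.seed(29)
  calls <- matrix(sample(0:2, 60, replace = TRUE), 10, 6,
                  dimnames = list(paste0("s", 1:10), paste0("rs", 1:6)))
  coded <- code_additive_dominance(genotype_matrix(calls))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_coded_genotypes(coded, p1, p2)
  back <- utils::read.delim(p1, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), unclass(coded), ignore_attr = TRUE)
  gm <- utils::read.delim(p2)
  expect_equal(gm$column, names(attr(coded, "groups")))
  expect_equal(gm$locus, unname(attr(coded, "groups")))
})

test_that("ancestry PCs score co-twins identically and separate clusters", {
  set.seed(28)
  n_fam <- 60
  # two ancestral clusters with different allele frequencies
  freqs <- cbind(runif(100, 0.1, 0.4), runif(100, 0.4, 0.8))
  cluster <- rep(1:2, each = n_fam / 2)
  founders <- t(vapply(seq_len(n_fam), function(i) {
    rbinom(100, 2, freqs[, cluster[i]])
  }, numeric(100)))
  # duplicate every founder as an MZ co-twin
  calls <- founders[rep(seq_len(n_fam), each = 2), ]
  rownames(calls) <- paste0("fam", rep(seq_len(n_fam), each = 2),
                            "_", rep(1:2, n_fam))
  g <- genotype_matrix(calls)
  fam <- rep(paste0("fam", seq_len(n_fam)), each = 2)
  pcs <- ancestry_pcs(g, k = 3, family_ids = fam)
  expect_equal(pcs[seq(1, 2 * n_fam, 2), ], pcs[seq(2, 2 * n_fam, 2), ],
               ignore_attr = TRUE)
  pc1 <- pcs[seq(1, 2 * n_fam, 2), 1]
  within_var <- mean(tapply(pc1, cluster, var))
  between <- diff(tapply(pc1, cluster, mean))^2
  expect_gt(between, within_var)          # PC1 separates the clusters
  # k = 0 gives an n x 0 matrix
  expect_equal(dim(ancestry_pcs(g, k = 0, family_ids = fam)),
               c(2 * n_fam, 0))
  expect_error(ancestry_pcs(g, k = 1000, family_ids = fam), "exceeds")
})
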