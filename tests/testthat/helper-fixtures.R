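# Shared fixtures, built lazily and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small twin cohort shared by residualize/pipeline tests
small_cohort <- function() {
  cached("small_cohort", simulate_cohort(simulation_config(
    n_pairs = 50L, n_loci = 200L, n_features = 80L,
    n_planted_snps = 4L, n_planted_features = 12L, seed = 101L)))
}

random_feature_table <- function(nf, ns, seed = 1, lengths = FALSE) {
  set.seed(seed)
  m <- matrix(rpois(nf * ns, 8) * rbinom(nf * ns, 1, 0.8), nf, ns,
              dimnames = list(sprintf("f%03d", seq_len(nf)),
                              sprintf("s%03d", seq_len(ns))))
  feature_table(m, lengths = if (lengths) {
    stats::setNames(sample(300:3000, nf, replace = TRUE), rownames(m))
  })
}

# brute-force two-sided Fisher p for a 2x2 table, by explicit enumeration
# of the hypergeometric support using log-binomial coefficients
fisher_p_bruteforce <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  row1 <- a + b
  col1 <- a + c_
  ks <- max(0, row1 + col1 - n):min(row1, col1)
  logp <- lchoose(col1, ks) + lchoose(n - col1, row1 - ks) -
    lchoose(n, row1)
  p_obs <- logp[ks == a]
  sum(exp(logp[logp <= p_obs + 1e-7]))
}

# dense-matrix GLS/BLUP oracle for the pair-block mixed model
dense_lmm_oracle <- function(X, y, w, family_id, sb2, se2) {
  n <- length(y)
  fam <- as.character(family_id)
  Z <- outer(fam, unique(fam), `==`) * 1
  V <- diag(se2 / w) + sb2 * tcrossprod(Z)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  m <- y - drop(X %*% beta)
  blup <- sb2 * drop(tcrossprod(Z) %*% Vi %*% m)
  list(beta = drop(beta), cond_resid = m - blup, marginal = m)
}
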