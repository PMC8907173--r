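sim_xy <- function(n, pL, q, n_sig_groups = min(5, pL),
                   n_sig_feats = min(15, q), strength = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 2 * pL), n)
  groups <- rep(paste0("g", seq_len(pL)), each = 2)
  colnames(X) <- paste0(groups, c("_a", "_d"))
  Y <- matrix(rnorm(n * q), n)
  colnames(Y) <- paste0("f", seq_len(q))
  u <- rnorm(n)
  X[, seq_len(2 * n_sig_groups)] <- X[, seq_len(2 * n_sig_groups)] +
    strength * u
  Y[, seq_len(n_sig_feats)] <- Y[, seq_len(n_sig_feats)] + strength * u
  list(X = scale(X, scale = FALSE), Y = scale(Y, scale = FALSE),
       groups = groups, u = u)
}

# KKT conditions for the group-lasso objective
# 0.5 ||z - Xb||^2 + lambda * sum_g ||b_g||
expect_group_lasso_kkt <- function(X, groups, z, lambda, b, tol = 1e-4) {
  r <- z - drop(X %*% b)
  for (g in unique(groups)) {
    cols <- which(groups == g)
    grad_g <- drop(crossprod(X[, cols, drop = FALSE], r))
    bg <- b[cols]
    if (sqrt(sum(bg^2)) > 1e-8) {
      expect_lt(max(abs(grad_g - lambda * bg / sqrt(sum(bg^2)))),
                tol * max(1, lambda))
    } else {
      expect_lte(sqrt(sum(grad_g^2)), lambda * (1 + tol))
    }
  }
}

test_that("group lasso reduces to least squares when unpenalized", {
  set.seed(61)
  n <- 100; pL <- 8
  X <- matrix(rnorm(n * 2 * pL), n)
  groups <- rep(paste0("g", 1:pL), each = 2)
  z <- rnorm(n)
  b <- group_lasso_step(X, groups, z, lambda1 = 0)
  ols <- qr.solve(X, z)
  expect_lt(max(abs(b - ols)), 1e-6)
  expect_error(group_lasso_step(X, groups, z, -1), "nonnegative")
})

test_that("group lasso shrinks to exact zero above the max penalty", {
  set.seed(62)
  n <- 80; pL <- 20
  X <- matrix(rnorm(n * 2 * pL), n)
  groups <- rep(paste0("g", 1:pL), each = 2)
  z <- rnorm(n)
  lmax <- max(sqrt(rowsum(drop(crossprod(X, z))^2, groups)))
  b <- group_lasso_step(X, groups, z, lambda1 = lmax * 1.001)
  expect_true(all(b == 0))
})

test_that("group lasso selects the generating group and satisfies KKT", {
  set.seed(63)
  n <- 200; pL <- 5
  X <- matrix(rnorm(n * 2 * pL), n)
  groups <- rep(paste0("g", 1:pL), each = 2)
  z <- drop(X[, 1:2] %*% c(1, 0.5)) + rnorm(n, 0, 0.3)
  lmax <- max(sqrt(rowsum(drop(crossprod(X, z))^2, groups)))
  b <- group_lasso_step(X, groups, z, lambda1 = 0.3 * lmax,
                        tol = 1e-12, max_iter = 20000)
  sel <- unique(groups[b != 0])
  expect_identical(sel, "g1")
  expect_group_lasso_kkt(X, groups, z, 0.3 * lmax, b)
  # coefficients within a group are jointly zero or jointly free
  nz <- tapply(b != 0, groups, sum)
  expect_true(all(nz %in% c(0L, 2L)))
})

# cyclic coordinate descent with closed-form elastic-net updates: an
# algorithmically independent solver for the same objective
elastic_net_cd_oracle <- function(Y, z, lambda2, mixing, iters = 3000) {
  b <- numeric(ncol(Y))
  cn <- colSums(Y^2)
  for (it in seq_len(iters)) {
    for (j in seq_len(ncol(Y))) {
      rho <- sum(Y[, j] * (z - Y[, -j, drop = FALSE] %*% b[-j]))
      b[j] <- sign(rho) * max(abs(rho) - lambda2 * mixing, 0) /
        (cn[j] + lambda2 * (1 - mixing))
    }
  }
  b
}

test_that("elastic net matches OLS, full shrinkage, and independent solvers", {
  set.seed(64)
  n <- 150; q <- 10
  Y <- matrix(rnorm(n * q), n)
  z <- drop(Y[, 1:3] %*% c(1, -0.5, 0.8)) + rnorm(n, 0, 0.5)
  a0 <- elastic_net_step(Y, z, lambda2 = 0)
  expect_lt(max(abs(a0 - qr.solve(Y, z))), 1e-6)
  ahuge <- elastic_net_step(Y, z, lambda2 = 1e6)
  expect_true(all(ahuge == 0))
  lambda2 <- 20; mixing <- 0.5
  mine <- elastic_net_step(Y, z, lambda2, mixing, tol = 1e-14,
                           max_iter = 50000)
  # KKT optimality of the returned solution
  grad <- drop(crossprod(Y, z - Y %*% mine)) -
    lambda2 * (1 - mixing) * mine
  nz <- mine != 0
  expect_lt(max(abs(grad[nz] - lambda2 * mixing * sign(mine[nz]))), 1e-5)
  expect_lte(max(abs(grad[!nz])), lambda2 * mixing * (1 + 1e-6))
  # coordinate-descent oracle agreement
  oracle <- elastic_net_cd_oracle(Y, z, lambda2, mixing)
  expect_equal(unname(mine), oracle, tolerance = 1e-6)
})

test_that("elastic net spreads weight over duplicated informative columns", {
  set.seed(65)
  n <- 200
  base <- rnorm(n)
  Y <- cbind(base, base, matrix(rnorm(n * 8), n))
  colnames(Y) <- paste0("f", 1:10)
  z <- base + rnorm(n, 0, 0.3)
  a <- elastic_net_step(Y, z, lambda2 = 30, mixing = 0.5)
  expect_gt(a[1], 0); expect_gt(a[2], 0)
  expect_lt(abs(a[1] - a[2]) / max(abs(a[1:2])), 0.05)
})

test_that("a planted identical column pair is found with near-perfect correlation", {
  set.seed(66)
  n <- 100
  shared <- rnorm(n)
  X <- cbind(shared + rnorm(n, 0, 0.01), matrix(rnorm(n * 9), n))
  groups <- paste0("g", rep(1:5, each = 2))
  colnames(X) <- paste0(groups, c("_a", "_d"))
  Y <- cbind(shared, matrix(rnorm(n * 7), n))
  colnames(Y) <- paste0("f", 1:8)
  comp <- scca_fit(scale(X, scale = FALSE), scale(Y, scale = FALSE),
                   groups, lambda1 = 0.5, lambda2 = 0.5)
  expect_true("g1" %in% comp$selected_snps)
  expect_true("f1" %in% comp$selected_features)
  expect_gt(comp$canonical_correlation, 0.99)
})

test_that("unpenalized low-dimensional sCCA equals classical CCA", {
  set.seed(67)
  n <- 200
  X <- matrix(rnorm(n * 10), n)
  colnames(X) <- paste0("g", rep(1:5, each = 2), c("_a", "_d"))
  Y <- matrix(rnorm(n * 8), n)
  colnames(Y) <- paste0("f", 1:8)
  Y[, 1] <- Y[, 1] + 0.5 * X[, 1]
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  comp <- scca_fit(Xc, Yc, rep(paste0("g", 1:5), each = 2),
                   lambda1 = 0, lambda2 = 0, tol = 1e-12,
                   max_iter = 2000)
  oracle <- cancor(Xc, Yc)
  expect_lt(abs(comp$canonical_correlation - oracle$cor[1]), 1e-4)
})

test_that("the block-coordinate objective is non-increasing and norms hold", {
  dat <- sim_xy(150, 40, 30, seed = 68)
  comp <- scca_fit(dat$X, dat$Y, dat$groups, lambda1 = 2, lambda2 = 2)
  expect_equal(comp$status, "ok")
  tr <- comp$objective_trace
  # non-increasing up to the inner-solver tolerance
  expect_true(all(diff(tr) <= 5e-6 * (abs(tr[-length(tr)]) + 1e-12)))
  expect_lt(tr[length(tr)], tr[1])
  u <- drop(dat$X %*% comp$beta)
  v <- drop(dat$Y %*% comp$alpha)
  expect_lt(abs(sqrt(sum(u^2)) - 1), 1e-8)
  expect_lt(abs(sqrt(sum(v^2)) - 1), 1e-8)
  # selected sets consistent with nonzero patterns
  expect_setequal(comp$selected_snps,
                  unique(dat$groups[comp$beta != 0]))
  expect_setequal(comp$selected_features,
                  names(comp$alpha)[comp$alpha != 0])
})

test_that("over-penalized fits return a flagged empty component", {
  dat <- sim_xy(80, 10, 10, seed = 69)
  comp <- scca_fit(dat$X, dat$Y, dat$groups, lambda1 = 1e6, lambda2 = 1e6)
  expect_equal(comp$status, "all_zero")
  expect_false(comp$converged)
  expect_true(all(comp$beta == 0))
})

test_that("deflation removes the extracted variate from both matrices", {
  dat <- sim_xy(120, 30, 25, seed = 70)
  comp <- scca_fit(dat$X, dat$Y, dat$groups, lambda1 = 1, lambda2 = 1)
  defl <- deflate(dat$X, dat$Y, comp)
  u <- drop(dat$X %*% comp$beta)
  v <- drop(dat$Y %*% comp$alpha)
  expect_lt(max(abs(crossprod(defl$Xres, u))), 1e-8)
  expect_lt(max(abs(crossprod(defl$Yres, v))), 1e-8)
  # cross-deflation removes the *other* side's variate from each matrix
  cross <- deflate(dat$X, dat$Y, comp, scheme = "cross")
  expect_lt(max(abs(crossprod(cross$Xres, v))), 1e-8)
  expect_lt(max(abs(crossprod(cross$Yres, u))), 1e-8)
  # rank-1 X: all columns proportional to u -> deflated X vanishes
  Xr1 <- outer(u, rnorm(ncol(dat$X)))
  colnames(Xr1) <- colnames(dat$X)
  defl2 <- deflate(Xr1, dat$Y, comp)
  expect_lt(max(abs(defl2$Xres)), 1e-8)
})

test_that("penalty tuning returns the only pair and prefers signal over noise", {
  dat <- sim_xy(100, 10, 10, seed = 71)
  one <- tibble::tibble(lambda1 = 3, lambda2 = 3)
  tuned <- tune_penalties(dat$X, dat$Y, dat$groups, grid = one, seed = 1)
  expect_equal(tuned$lambda1, 3)
  expect_equal(tuned$lambda2, 3)
  expect_equal(nrow(tuned$cv_table), 5)
})

test_that("tuning on pure noise yields a near-zero held-out correlation", {
  set.seed(72)
  n <- 400
  X <- scale(matrix(rnorm(n * 40), n), scale = FALSE)
  colnames(X) <- paste0("g", rep(1:20, each = 2), c("_a", "_d"))
  Y <- scale(matrix(rnorm(n * 30), n), scale = FALSE)
  colnames(Y) <- paste0("f", 1:30)
  tuned <- tune_penalties(X, Y, rep(paste0("g", 1:20), each = 2),
                          seed = 3)
  chosen <- dplyr::filter(tuned$cv_means,
                          .data$lambda1 == tuned$lambda1,
                          .data$lambda2 == tuned$lambda2)
  expect_lt(abs(chosen$mean_cor), 2 / sqrt(n))
})

test_that("tuning finds penalties that generalize on planted signal", {
  dat <- sim_xy(200, 50, 40, strength = 1, seed = 73)
  tuned <- tune_penalties(dat$X, dat$Y, dat$groups, seed = 2)
  best <- max(tuned$cv_means$mean_cor)
  expect_gt(best, 0.2)
})

test_that("final CCA refit matches classical oracles", {
  set.seed(74)
  n <- 150
  dat <- sim_xy(n, 10, 10, seed = 74)
  # one column each side: correlation = |pearson|
  comp1 <- final_cca(dat$X, dat$Y, dat$groups, "g1", "f1")
  expect_equal(comp1$canonical_correlation,
               abs(cor(dat$X[, 1:2] %*% comp1$beta[1:2],
                       dat$Y[, 1, drop = FALSE])[1]),
               tolerance = 1e-10)
  r1 <- abs(cor(dat$X %*% comp1$beta, dat$Y %*% comp1$alpha))[1]
  expect_equal(comp1$canonical_correlation, r1, tolerance = 1e-10)
  # low-dimensional selection vs cancor
  comp2 <- final_cca(dat$X, dat$Y, dat$groups,
                     paste0("g", 1:4), paste0("f", 1:5))
  xcols <- which(dat$groups %in% paste0("g", 1:4))
  oracle <- cancor(dat$X[, xcols], dat$Y[, 1:5])
  expect_lt(abs(comp2$canonical_correlation - oracle$cor[1]), 1e-8)
  expect_error(final_cca(dat$X, dat$Y, dat$groups, character(0), "f1"),
               "empty")
})

test_that("ridge stabilization changes well-conditioned refits negligibly", {
  dat <- sim_xy(150, 10, 10, seed = 75)
  c_plain <- tweediecca:::classical_cca(dat$X[, 1:6], dat$Y[, 1:5],
                                        ridge_eps = 0)
  c_ridge <- tweediecca:::classical_cca(dat$X[, 1:6], dat$Y[, 1:5],
                                        ridge_eps = 1e-8)
  expect_lt(abs(c_plain$cor - c_ridge$cor), 1e-6)
})

test_that("run_scca extracts ordered components with the group contract", {
  set.seed(76)
  n <- 250
  u1 <- rnorm(n); u2 <- rnorm(n)
  X <- matrix(rnorm(n * 60), n)
  groups <- rep(paste0("g", 1:30), each = 2)
  colnames(X) <- paste0(groups, c("_a", "_d"))
  X[, 1:6] <- X[, 1:6] + 1.5 * u1       # groups 1-3: strong factor
  X[, 7:10] <- X[, 7:10] + 0.9 * u2     # groups 4-5: weaker factor
  Y <- matrix(rnorm(n * 40), n)
  colnames(Y) <- paste0("f", 1:40)
  Y[, 1:8] <- Y[, 1:8] + 1.5 * u1
  Y[, 9:14] <- Y[, 9:14] + 0.9 * u2
  model <- run_scca(X, Y, groups = groups, n_components = 2, seed = 4)
  expect_equal(length(model$components), 2)
  g1 <- glance(model)
  expect_gt(g1$canonical_correlation[1], g1$canonical_correlation[2])
  # component 1 targets the strong factor, component 2 the weak one
  s1 <- model$sparse_components[[1]]$selected_features
  s2 <- model$sparse_components[[2]]$selected_features
  expect_gt(mean(paste0("f", 1:8) %in% s1), 0.5)
  expect_lt(mean(paste0("f", 1:8) %in% s2), 0.2)
  expect_gt(mean(paste0("f", 9:14) %in% s2), 0.5)
  # group contract on the sparse weights
  b <- model$sparse_components[[1]]$beta
  nz <- tapply(b != 0, groups, sum)
  expect_true(all(nz %in% c(0L, 2L)))
  # tidy/glance structure
  td <- tidy(model)
  expect_setequal(unique(td$side), c("genotype", "abundance"))
  expect_equal(nrow(td), 2 * (ncol(X) + ncol(Y)))
})

test_that("single-component runs skip deflation", {
  dat <- sim_xy(100, 15, 12, seed = 77)
  model <- run_scca(dat$X, dat$Y, groups = dat$groups, n_components = 1,
                    seed = 5)
  expect_equal(length(model$components), 1)
  expect_false(any(grepl("deflated", model$deflation_history)))
})

test_that("selection summary applies inclusion-exclusion", {
  s <- selection_summary(134, 417, 66, 655)
  expect_equal(s$n_union, 485)
  expect_equal(s$pct_union, 74.05)
  expect_equal(s$pct_component1, 20.46)
  s2 <- selection_summary(168, 171, 0, 12813)
  expect_equal(s2$n_union, 339)
  expect_equal(s2$pct_union, 2.65)
})
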