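# Sparse canonical correlation analysis between genotype and abundance
# residual matrices. The objective is
#
#   argmin ||X beta - Y alpha||_2^2 + lambda1 * pen1(beta) + lambda2 * pen2(alpha)
#     s.t. ||X beta||_2 = ||Y alpha||_2 = 1
#
# with pen1 the group lasso over the additive/dominance column pair of each
# locus and pen2 the elastic net over microbial features. It is solved by
# block coordinate descent: alternating penalized regressions of each side on
# the other's canonical variate, rescaling the fitted variate to unit norm
# after each half-step. Both penalized regressions are solved by FISTA
# (proximal gradient with momentum); the group-lasso prox is blockwise soft
# thresholding, the elastic-net prox is scalar soft thresholding with ridge
# shrinkage. KKT-condition checks and an algorithmically independent
# coordinate-descent solver serve as oracles in the test suite.

# largest eigenvalue of X'X by power iteration, inflated 5% so that the
# FISTA step 1/L is a safe upper bound
spectral_norm_sq <- function(X, iters = 30L) {
  v <- rep(1 / sqrt(ncol(X)), ncol(X))
  for (i in seq_len(iters)) {
    z <- drop(crossprod(X, X %*% v))
    nz <- sqrt(sum(z^2))
    if (nz == 0) return(1)
    v <- z / nz
  }
  1.05 * drop(crossprod(X %*% v))
}

# X %*% v exploiting sparsity in v (proximal iterates are mostly zero)
sparse_mv <- function(X, v) {
  nz <- which(v != 0)
  if (length(nz) == 0L) return(numeric(nrow(X)))
  if (length(nz) > ncol(X) / 3L) return(drop(X %*% v))
  drop(X[, nz, drop = FALSE] %*% v[nz])
}

group_soft_threshold <- function(u, group, thr) {
  nrm <- sqrt(rowsum(u^2, group, reorder = FALSE))
  scale <- pmax(0, 1 - thr / pmax(nrm[, 1L], 1e-300))
  u * scale[match(group, rownames(nrm))]
}

#' Group-lasso regression step
#'
#' Solves `min_b 0.5 * ||z - X b||^2 + lambda1 * sum_g ||b_g||_2`, where the
#' groups are the additive/dominance column pairs of each locus, so a locus's
#' coefficients are jointly zero or jointly free. All groups here have equal
#' size, so no group-size weighting is applied. Solved by FISTA; with
#' `lambda1 = 0` and a full-rank low-dimensional design the solution is
#' ordinary least squares (computed directly in that case).
#'
#' @param X Centered design matrix (samples x coded columns).
#' @param groups Character vector mapping each column to its group (locus).
#' @param z Target vector.
#' @param lambda1 Nonnegative group-lasso penalty.
#' @param tol,max_iter Convergence controls.
#' @param init Optional warm-start coefficient vector.
#' @param L Optional precomputed squared spectral norm of `X` (the FISTA
#'   Lipschitz constant), reused across calls on the same matrix.
#' @return Coefficient vector `b` (named by column).
#' @export
group_lasso_step <- function(X, groups, z, lambda1, tol = 1e-8,
                             max_iter = 1000L, init = NULL, L = NULL) {
  if (lambda1 < 0) stop("`lambda1` must be nonnegative")
  if (lambda1 == 0 && ncol(X) <= nrow(X)) {
    fit <- stats::lm.fit(X, z)
    b <- fit$coefficients
    b[is.na(b)] <- 0
    return(b)
  }
  if (is.null(L)) L <- spectral_norm_sq(X)
  b <- if (is.null(init)) numeric(ncol(X)) else init
  v <- b
  tprev <- 1
  Xty <- drop(crossprod(X, z))
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    grad <- drop(crossprod(X, sparse_mv(X, v))) - Xty
    u <- v - grad / L
    b_new <- drop(group_soft_threshold(u, groups, lambda1 / L))
    tnew <- (1 + sqrt(1 + 4 * tprev^2)) / 2
    v <- b_new + ((tprev - 1) / tnew) * (b_new - b)
    b <- b_new
    tprev <- tnew
    if (it %% 5L == 0L || it == max_iter) {
      r <- z - sparse_mv(X, b)
      obj <- 0.5 * sum(r^2) +
        lambda1 * sum(sqrt(rowsum(b^2, groups, reorder = FALSE)))
      if (abs(obj_prev - obj) < tol * (abs(obj) + 1e-10)) break
      obj_prev <- obj
    }
  }
  names(b) <- colnames(X)
  b
}

#' Elastic-net regression step
#'
#' Solves `min_a 0.5 * ||z - Y a||^2 +
#' lambda2 * (mixing * ||a||_1 + (1 - mixing)/2 * ||a||_2^2)`. The l1 part
#' selects features; the l2 part spreads weight over correlated features
#' (the grouping effect that makes the penalty suit co-abundant gene
#' families). Solved by FISTA with the ridge term in the smooth part.
#'
#' @param Y Centered matrix (samples x features).
#' @param z Target vector.
#' @param lambda2 Nonnegative penalty strength.
#' @param mixing Elastic-net mixing in (0, 1]; 1 is the lasso. Default 0.5.
#' @param tol,max_iter Convergence controls.
#' @param init Optional warm-start coefficient vector.
#' @param L Optional precomputed squared spectral norm of `Y`.
#' @return Coefficient vector `a` (named by feature).
#' @export
elastic_net_step <- function(Y, z, lambda2, mixing = 0.5, tol = 1e-8,
                             max_iter = 1000L, init = NULL, L = NULL) {
  if (lambda2 < 0) stop("`lambda2` must be nonnegative")
  if (mixing <= 0 || mixing > 1) stop("`mixing` must be in (0, 1]")
  if (lambda2 == 0 && ncol(Y) <= nrow(Y)) {
    fit <- stats::lm.fit(Y, z)
    a <- fit$coefficients
    a[is.na(a)] <- 0
    return(a)
  }
  ridge <- lambda2 * (1 - mixing)
  if (is.null(L)) L <- spectral_norm_sq(Y)
  L <- L + ridge
  a <- if (is.null(init)) numeric(ncol(Y)) else init
  v <- a
  tprev <- 1
  Yty <- drop(crossprod(Y, z))
  obj_prev <- Inf
  thr <- lambda2 * mixing
  for (it in seq_len(max_iter)) {
    grad <- drop(crossprod(Y, sparse_mv(Y, v))) - Yty + ridge * v
    u <- v - grad / L
    a_new <- sign(u) * pmax(abs(u) - thr / L, 0)
    tnew <- (1 + sqrt(1 + 4 * tprev^2)) / 2
    v <- a_new + ((tprev - 1) / tnew) * (a_new - a)
    a <- a_new
    tprev <- tnew
    if (it %% 5L == 0L || it == max_iter) {
      r <- z - sparse_mv(Y, a)
      obj <- 0.5 * sum(r^2) + thr * sum(abs(a)) + ridge / 2 * sum(a^2)
      if (abs(obj_prev - obj) < tol * (abs(obj) + 1e-10)) break
      obj_prev <- obj
    }
  }
  names(a) <- colnames(Y)
  a
}

scca_objective <- function(u, v, beta, alpha, groups, lambda1, lambda2,
                           mixing) {
  sum((u - v)^2) +
    lambda1 * sum(sqrt(rowsum(beta^2, groups, reorder = FALSE))) +
    lambda2 * (mixing * sum(abs(alpha)) +
                 (1 - mixing) / 2 * sum(alpha^2))
}

empty_component <- function(X, Y, groups, status) {
  structure(list(beta = stats::setNames(numeric(ncol(X)), colnames(X)),
                 alpha = stats::setNames(numeric(ncol(Y)), colnames(Y)),
                 selected_snps = character(0),
                 selected_features = character(0),
                 canonical_correlation = NA_real_,
                 n_iterations = 0L, converged = FALSE,
                 status = status, objective_trace = numeric(0)),
            class = "scca_component")
}

# leading left singular vector of Y'X by matrix-free power iteration on
# (Y'X)(Y'X)' = Y'X X'Y; deterministic start so fits are reproducible
init_alpha <- function(X, Y, iters = 50L) {
  a <- rep(1 / sqrt(ncol(Y)), ncol(Y))
  for (i in seq_len(iters)) {
    v1 <- Y %*% a
    v2 <- drop(crossprod(X, v1))
    v3 <- X %*% v2
    a_new <- drop(crossprod(Y, v3))
    na <- sqrt(sum(a_new^2))
    if (na == 0) return(a)
    a_new <- a_new / na
    if (max(abs(a_new - a)) < 1e-10) {
      a <- a_new
      break
    }
    a <- a_new
  }
  a
}

#' Fit one sparse canonical component
#'
#' Alternates a group-lasso regression of the abundance variate on the coded
#' genotype columns and an elastic-net regression of the genotype variate on
#' the microbial features, rescaling each fitted variate to unit l2 norm
#' after its half-step, until the relative change of the penalized objective
#' falls below `tol`. Initialization is deterministic: the leading singular
#' vector of the cross-product matrix `Y'X`.
#'
#' Weight magnitudes are returned for completeness but should be read as
#' selection indicators only (zero vs nonzero); the penalties shrink
#' magnitudes incomparably across features.
#'
#' @param Xres Genotype residual matrix (samples x coded columns), centered.
#' @param Yres Abundance residual matrix (samples x features), centered.
#' @param groups Column-to-locus map for `Xres`.
#' @param lambda1 Group-lasso penalty.
#' @param lambda2 Elastic-net penalty.
#' @param mixing Elastic-net mixing; default 0.5.
#' @param tol Relative objective tolerance; default 1e-6.
#' @param max_iter Maximum alternations; default 200.
#' @param inner_max_iter Iteration cap for each inner FISTA solve; default
#'   1000 (cross-validation fits use a smaller cap).
#' @param init Optional warm start: a list with `beta` and/or `alpha`.
#' @return An `scca_component` with weights `beta`, `alpha`, the selected
#'   locus and feature sets, the canonical correlation, iteration count,
#'   convergence flag and objective trace. If a penalty shrinks an entire
#'   side to zero the component is returned empty with
#'   `status = "all_zero"`.
#' @export
scca_fit <- function(Xres, Yres, groups, lambda1, lambda2, mixing = 0.5,
                     tol = 1e-6, max_iter = 200L, inner_max_iter = 1000L,
                     init = NULL) {
  X <- unclass(Xres); Y <- unclass(Yres)
  if (nrow(X) != nrow(Y)) stop("X and Y must share sample rows")
  if (nrow(X) < 10L) stop("need at least 10 samples")
  groups <- as.character(rep_len(groups, ncol(X)))
  alpha <- init$alpha %||% init_alpha(X, Y)
  v <- drop(Y %*% alpha)
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(empty_component(X, Y, groups, "degenerate_init"))
  alpha <- alpha / nv; v <- v / nv
  beta <- init$beta %||% numeric(ncol(X))
  u <- numeric(nrow(X))
  Lx <- init$Lx %||% spectral_norm_sq(X)
  Ly <- init$Ly %||% spectral_norm_sq(Y)
  obj_trace <- numeric(0)
  obj_prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    beta <- group_lasso_step(X, groups, v, lambda1, init = beta, L = Lx,
                             max_iter = inner_max_iter)
    u_raw <- drop(X %*% beta)
    nu <- sqrt(sum(u_raw^2))
    if (nu < 1e-12) {
      return(empty_component(X, Y, groups, "all_zero"))
    }
    beta <- beta / nu; u <- u_raw / nu
    alpha <- elastic_net_step(Y, u, lambda2, mixing, init = alpha, L = Ly,
                              max_iter = inner_max_iter)
    v_raw <- drop(Y %*% alpha)
    nv <- sqrt(sum(v_raw^2))
    if (nv < 1e-12) {
      return(empty_component(X, Y, groups, "all_zero"))
    }
    alpha <- alpha / nv; v <- v_raw / nv
    obj <- scca_objective(u, v, beta, alpha, groups, lambda1, lambda2,
                          mixing)
    obj_trace <- c(obj_trace, obj)
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) < tol * (abs(obj) + 1e-12)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  sel_groups <- unique(groups[beta != 0])
  structure(list(beta = beta, alpha = alpha,
                 selected_snps = sel_groups,
                 selected_features = names(alpha)[alpha != 0],
                 canonical_correlation = stats::cor(u, v),
                 n_iterations = it, converged = converged,
                 status = "ok", objective_trace = obj_trace),
            class = "scca_component")
}

#' @export
print.scca_component <- function(x, ...) {
  cat(sprintf(paste0("<scca_component> status=%s, cor=%.3f, ",
                     "%d loci, %d features, %d iterations%s\n"),
              x$status, x$canonical_correlation,
              length(x$selected_snps), length(x$selected_features),
              x$n_iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Default penalty grid
#'
#' Twelve penalty pairs: 3 group-lasso strengths times 4 elastic-net
#' strengths, log-spaced from 1% to 100% of each side's analytic maximum
#' penalty (the smallest value that zeroes the respective side at the
#' deterministic initialization).
#'
#' @param Xres,Yres Residual matrices.
#' @param groups Column-to-locus map for `Xres`.
#' @param mixing Elastic-net mixing used for the l1 threshold.
#' @param n_lambda1,n_lambda2 Grid sizes (defaults 3 and 4).
#' @return A tibble with columns `lambda1`, `lambda2` (12 rows by default).
#' @export
default_penalty_grid <- function(Xres, Yres, groups, mixing = 0.5,
                                 n_lambda1 = 3L, n_lambda2 = 4L) {
  X <- unclass(Xres); Y <- unclass(Yres)
  groups <- as.character(rep_len(groups, ncol(X)))
  alpha0 <- init_alpha(X, Y)
  v0 <- drop(Y %*% alpha0)
  v0 <- v0 / sqrt(sum(v0^2))
  sc <- drop(crossprod(X, v0))
  l1max <- max(sqrt(rowsum(sc^2, groups, reorder = FALSE)))
  # X-side variate at lambda1 = 0 direction for the Y-side threshold
  b0 <- group_lasso_step(X, groups, v0, lambda1 = 0.01 * l1max)
  u0 <- drop(X %*% b0)
  nu0 <- sqrt(sum(u0^2))
  if (nu0 < 1e-12) {
    u0 <- v0
  } else {
    u0 <- u0 / nu0
  }
  l2max <- max(abs(crossprod(Y, u0))) / mixing
  grid <- expand.grid(
    lambda1 = exp(seq(log(0.01 * l1max), log(l1max),
                      length.out = n_lambda1)),
    lambda2 = exp(seq(log(0.01 * l2max), log(l2max),
                      length.out = n_lambda2)))
  tibble::as_tibble(grid)
}

#' Tune the penalty pair by cross-validation
#'
#' Splits samples into `folds` folds, fits each penalty pair on the training
#' folds and evaluates the correlation of the held-out canonical variates
#' `cor(X_test beta, Y_test alpha)`. The pair maximizing the mean held-out
#' correlation wins; ties go to the sparser pair (larger `lambda1 +
#' lambda2`). Folds with a zero-variance or empty variate score 0.
#'
#' @param Xres,Yres Residual matrices (samples aligned).
#' @param groups Column-to-locus map.
#' @param grid Penalty grid tibble (`lambda1`, `lambda2`); default
#'   [default_penalty_grid()].
#' @param folds Number of CV folds; default 5.
#' @param seed Integer seed for the fold split.
#' @param mixing Elastic-net mixing.
#' @param max_iter Alternation cap per CV fit (default 10; the selection
#'   surface stabilizes long before full convergence).
#' @param family_id Optional family labels, one per sample. When given,
#'   whole families are assigned to folds so co-twins never straddle a
#'   train/test split — otherwise any residual within-family correlation
#'   lets overfit models score spuriously well on held-out co-twins.
#' @return List with `lambda1`, `lambda2`, and `cv_table` (tibble of
#'   per-pair, per-fold held-out correlations).
#' @export
tune_penalties <- function(Xres, Yres, groups, grid = NULL, folds = 5L,
                           seed = 1L, mixing = 0.5, max_iter = 10L,
                           family_id = NULL) {
  X <- unclass(Xres); Y <- unclass(Yres)
  groups <- as.character(rep_len(groups, ncol(X)))
  if (is.null(grid)) grid <- default_penalty_grid(X, Y, groups, mixing)
  if (nrow(grid) < 1L) stop("penalty grid is empty")
  n <- nrow(X)
  if (is.null(family_id)) {
    fold_id <- with_local_seed(seed, sample(rep_len(seq_len(folds), n)))
  } else {
    fam <- as.character(rep_len(family_id, n))
    ufam <- unique(fam)
    fam_fold <- with_local_seed(seed,
                                sample(rep_len(seq_len(folds),
                                               length(ufam))))
    fold_id <- fam_fold[match(fam, ufam)]
  }
  # strongest penalties first so warm starts move from sparse to dense
  ord <- order(-(grid$lambda1 + grid$lambda2))
  rows <- vector("list", nrow(grid) * folds)
  k <- 0L
  for (f in seq_len(folds)) {
    test <- fold_id == f
    Xtr <- scale(X[!test, , drop = FALSE], scale = FALSE)
    Ytr <- scale(Y[!test, , drop = FALSE], scale = FALSE)
    warm <- list(Lx = spectral_norm_sq(Xtr), Ly = spectral_norm_sq(Ytr))
    for (gi in ord) {
      comp <- scca_fit(Xtr, Ytr, groups, grid$lambda1[gi],
                       grid$lambda2[gi], mixing = mixing,
                       max_iter = max_iter, inner_max_iter = 50L,
                       init = warm)
      cv_cor <- 0
      if (comp$status == "ok") {
        warm$beta <- comp$beta
        warm$alpha <- comp$alpha
        ut <- drop(X[test, , drop = FALSE] %*% comp$beta)
        vt <- drop(Y[test, , drop = FALSE] %*% comp$alpha)
        if (stats::sd(ut) > 0 && stats::sd(vt) > 0) {
          cv_cor <- stats::cor(ut, vt)
        }
      }
      k <- k + 1L
      rows[[k]] <- tibble::tibble(lambda1 = grid$lambda1[gi],
                                  lambda2 = grid$lambda2[gi],
                                  fold = f, cv_cor = cv_cor)
    }
  }
  cv_table <- dplyr::bind_rows(rows)
  means <- cv_table |>
    dplyr::group_by(.data$lambda1, .data$lambda2) |>
    dplyr::summarise(mean_cor = mean(.data$cv_cor), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_cor),
                   dplyr::desc(.data$lambda1 + .data$lambda2))
  list(lambda1 = means$lambda1[1L], lambda2 = means$lambda2[1L],
       cv_table = cv_table, cv_means = means)
}

#' Deflate residual matrices against an extracted component
#'
#' By default regresses every column of each matrix on that matrix's own
#' canonical variate and keeps the residual, then re-centers columns, so
#' subsequent components explore structure orthogonal to what has been
#' found. `scheme = "cross"` instead regresses each matrix on the *other*
#' side's variate (removing from the SNP matrix what the abundance variate
#' explains, and vice versa).
#'
#' @param Xres,Yres Residual matrices.
#' @param comp An `scca_component` with nonzero variates.
#' @param scheme `"self"` (default) or `"cross"`.
#' @return List with deflated `Xres` and `Yres`.
#' @export
deflate <- function(Xres, Yres, comp, scheme = c("self", "cross")) {
  scheme <- match.arg(scheme)
  X <- unclass(Xres); Y <- unclass(Yres)
  u <- drop(X %*% comp$beta)
  v <- drop(Y %*% comp$alpha)
  if (sum(u^2) < 1e-24 || sum(v^2) < 1e-24) {
    stop("cannot deflate against a zero-norm variate")
  }
  if (scheme == "cross") {
    tmp <- u; u <- v; v <- tmp
  }
  Xd <- X - outer(u, drop(crossprod(X, u)) / sum(u^2))
  Yd <- Y - outer(v, drop(crossprod(Y, v)) / sum(v^2))
  Xd <- scale(Xd, scale = FALSE)
  Yd <- scale(Yd, scale = FALSE)
  dimnames(Xd) <- dimnames(X); dimnames(Yd) <- dimnames(Y)
  attr(Xd, "scaled:center") <- NULL
  attr(Yd, "scaled:center") <- NULL
  list(Xres = Xd, Yres = Yd)
}

# classical CCA by whitened SVD with optional ridge stabilization
classical_cca <- function(Xs, Ys, ridge_eps = 0) {
  n <- nrow(Xs)
  Sxx <- crossprod(Xs) / (n - 1)
  Syy <- crossprod(Ys) / (n - 1)
  Sxy <- crossprod(Xs, Ys) / (n - 1)
  if (ridge_eps > 0) {
    diag(Sxx) <- diag(Sxx) + ridge_eps * mean(diag(Sxx))
    diag(Syy) <- diag(Syy) + ridge_eps * mean(diag(Syy))
  }
  ex <- eigen(Sxx, symmetric = TRUE)
  ey <- eigen(Syy, symmetric = TRUE)
  tolx <- max(ex$values) * 1e-10
  toly <- max(ey$values) * 1e-10
  kx <- ex$values > tolx
  ky <- ey$values > toly
  Wx <- ex$vectors[, kx, drop = FALSE] %*%
    diag(1 / sqrt(ex$values[kx]), sum(kx))
  Wy <- ey$vectors[, ky, drop = FALSE] %*%
    diag(1 / sqrt(ey$values[ky]), sum(ky))
  M <- t(Wx) %*% Sxy %*% Wy
  sv <- svd(M, nu = 1L, nv = 1L)
  list(a = drop(Wx %*% sv$u), b = drop(Wy %*% sv$v), cor = sv$d[1L])
}

#' Refit classical CCA on the selected features
#'
#' After sparse selection, the reduced column sets are small enough for an
#' ordinary canonical correlation fit, which gives the reported component.
#' When the selected column count approaches the sample count the covariance
#' blocks are ridge-stabilized by adding `ridge_eps` times the mean diagonal
#' to each block's diagonal.
#'
#' @param Xres,Yres Residual matrices.
#' @param groups Column-to-locus map for `Xres`.
#' @param selected_snps Locus identifiers selected by the sparse fit.
#' @param selected_features Feature identifiers selected by the sparse fit.
#' @param ridge_eps Diagonal shrinkage applied when columns >= samples;
#'   default 1e-3.
#' @return An `scca_component` with refined weights (zeros off-selection),
#'   unit-norm variates and the refined canonical correlation.
#' @export
final_cca <- function(Xres, Yres, groups, selected_snps, selected_features,
                      ridge_eps = 1e-3) {
  if (length(selected_snps) == 0 || length(selected_features) == 0) {
    stop("cannot refit CCA with an empty selection")
  }
  X <- unclass(Xres); Y <- unclass(Yres)
  groups <- as.character(rep_len(groups, ncol(X)))
  xcols <- which(groups %in% selected_snps)
  ycols <- which(colnames(Y) %in% selected_features)
  Xs <- X[, xcols, drop = FALSE]
  Ys <- Y[, ycols, drop = FALSE]
  eps <- if (length(xcols) >= nrow(X) || length(ycols) >= nrow(Y)) {
    ridge_eps
  } else {
    0
  }
  cc <- classical_cca(Xs, Ys, ridge_eps = eps)
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  alpha <- stats::setNames(numeric(ncol(Y)), colnames(Y))
  beta[xcols] <- cc$a
  alpha[ycols] <- cc$b
  u <- drop(X %*% beta); v <- drop(Y %*% alpha)
  beta <- beta / sqrt(sum(u^2)); alpha <- alpha / sqrt(sum(v^2))
  structure(list(beta = beta, alpha = alpha,
                 selected_snps = selected_snps,
                 selected_features = selected_features,
                 canonical_correlation =
                   stats::cor(u, v),
                 n_iterations = 1L, converged = TRUE,
                 status = "ok", objective_trace = numeric(0)),
            class = "scca_component")
}

#' Run the full sparse CCA workflow
#'
#' Tunes the penalty pair once by cross-validation (the single
#' tuning-parameter optimization step of the workflow), then for each
#' requested component fits the sparse component with that pair, refits
#' classical CCA on the selected columns, and deflates both matrices
#' against the sparse component's variates before extracting the next
#' component. An all-zero component truncates the sequence.
#'
#' @param Xres Genotype residual matrix (samples x coded columns) with a
#'   `groups` attribute, or supply `groups` explicitly.
#' @param Yres Abundance residual matrix (samples x features).
#' @param groups Column-to-locus map (defaults to `attr(Xres, "groups")`).
#' @param grid Optional fixed penalty grid; by default the 12-pair grid is
#'   rebuilt from the current matrices for every component.
#' @param n_components Number of components to extract; default 2.
#' @param folds CV folds; default 5.
#' @param seed Integer seed controlling the CV splits.
#' @param mixing Elastic-net mixing; default 0.5.
#' @param family_id Optional per-sample family labels for family-wise CV
#'   folds (see [tune_penalties()]).
#' @return An `scca_model`: list of refined components, the sparse
#'   components, chosen penalty pairs, CV tables and deflation history.
#'   `tidy()` returns the per-feature weight/selection table; `glance()`
#'   summarises components.
#' @export
run_scca <- function(Xres, Yres, groups = attr(Xres, "groups"), grid = NULL,
                     n_components = 2L, folds = 5L, seed = 1L,
                     mixing = 0.5, family_id = NULL) {
  if (n_components < 1L) stop("`n_components` must be at least 1")
  if (is.null(groups)) stop("no column-to-locus group map supplied")
  if (!is.null(rownames(Xres)) && !is.null(rownames(Yres)) &&
      !identical(rownames(Xres), rownames(Yres))) {
    stop("Xres and Yres sample rows are not aligned")
  }
  X <- scale(unclass(Xres), scale = FALSE)
  Y <- scale(unclass(Yres), scale = FALSE)
  attr(X, "scaled:center") <- NULL
  attr(Y, "scaled:center") <- NULL
  groups <- as.character(rep_len(groups, ncol(X)))
  components <- list()
  raw_components <- list()
  penalties <- list()
  cv_tables <- list()
  deflation_history <- character(0)
  tuned <- tune_penalties(X, Y, groups, grid = grid, folds = folds,
                          seed = seed, mixing = mixing,
                          family_id = family_id)
  for (comp_i in seq_len(n_components)) {
    comp <- scca_fit(X, Y, groups, tuned$lambda1, tuned$lambda2,
                     mixing = mixing)
    if (comp$status != "ok" || length(comp$selected_snps) == 0 ||
        length(comp$selected_features) == 0) {
      deflation_history <- c(deflation_history,
                             sprintf("component %d: %s (truncated)",
                                     comp_i, comp$status))
      break
    }
    refined <- final_cca(X, Y, groups, comp$selected_snps,
                         comp$selected_features)
    components[[comp_i]] <- refined
    raw_components[[comp_i]] <- comp
    penalties[[comp_i]] <- c(lambda1 = tuned$lambda1,
                             lambda2 = tuned$lambda2)
    if (comp_i == 1L) {
      cv_tables[[1L]] <- dplyr::mutate(tuned$cv_table, component = 1L)
    }
    if (comp_i < n_components) {
      defl <- deflate(X, Y, comp)
      X <- defl$Xres
      Y <- defl$Yres
      deflation_history <- c(deflation_history,
                             sprintf("component %d: deflated both matrices",
                                     comp_i))
    }
  }
  structure(list(components = components,
                 sparse_components = raw_components,
                 penalty_pairs = penalties,
                 cv_table = dplyr::bind_rows(cv_tables),
                 deflation_history = deflation_history,
                 groups = groups,
                 mixing = mixing, seed = seed),
            class = "scca_model")
}

#' @export
print.scca_model <- function(x, ...) {
  cat(sprintf("<scca_model> %d component(s)\n", length(x$components)))
  for (i in seq_along(x$components)) {
    c1 <- x$components[[i]]
    cat(sprintf("  [%d] cor = %.3f | %d loci, %d features (l1 = %.3g, l2 = %.3g)\n",
                i, c1$canonical_correlation, length(c1$selected_snps),
                length(c1$selected_features),
                x$penalty_pairs[[i]]["lambda1"],
                x$penalty_pairs[[i]]["lambda2"]))
  }
  invisible(x)
}

#' @export
tidy.scca_model <- function(x, ...) {
  purrr::imap_dfr(x$components, function(comp, i) {
    dplyr::bind_rows(
      tibble::tibble(component = i, side = "genotype",
                     id = names(comp$beta), group = x$groups,
                     weight = unname(comp$beta),
                     selected = x$groups %in% comp$selected_snps),
      tibble::tibble(component = i, side = "abundance",
                     id = names(comp$alpha), group = NA_character_,
                     weight = unname(comp$alpha),
                     selected = unname(comp$alpha) != 0))
  })
}

#' @export
glance.scca_model <- function(x, ...) {
  purrr::imap_dfr(x$components, function(comp, i) {
    tibble::tibble(component = i,
                   canonical_correlation = comp$canonical_correlation,
                   n_selected_snps = length(comp$selected_snps),
                   n_selected_features = length(comp$selected_features),
                   lambda1 = unname(x$penalty_pairs[[i]]["lambda1"]),
                   lambda2 = unname(x$penalty_pairs[[i]]["lambda2"]))
  })
}

#' @export
autoplot.scca_model <- function(object, ...) {
  cv <- object$cv_table |>
    dplyr::group_by(.data$component, .data$lambda1, .data$lambda2) |>
    dplyr::summarise(mean_cor = mean(.data$cv_cor), .groups = "drop")
  ggplot2::ggplot(cv, ggplot2::aes(factor(signif(.data$lambda1, 3)),
                                   factor(signif(.data$lambda2, 3)),
                                   fill = .data$mean_cor)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~component, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "group-lasso penalty", y = "elastic-net penalty",
                  fill = "mean held-out\ncorrelation")
}

#' Selection counts and percentages across two components
#'
#' Summarizes a two-component selection by inclusion-exclusion: the union
#' count is `n1 + n2 - overlap`, and each count is expressed as a percentage
#' of the background universe (printed to two decimals, as conventionally
#' reported).
#'
#' @param n1,n2 Features selected by components 1 and 2.
#' @param overlap Features selected by both.
#' @param background Size of the feature universe.
#' @return One-row tibble with the union count and the three percentages.
#' @export
#' @examples
#' selection_summary(134, 417, 66, 655) # union 485, 74.05%
selection_summary <- function(n1, n2, overlap, background) {
  stopifnot(overlap <= n1, overlap <= n2, n1 <= background,
            n2 <= background)
  union_n <- n1 + n2 - overlap
  tibble::tibble(n_component1 = n1, n_component2 = n2,
                 n_overlap = overlap, n_union = union_n,
                 pct_component1 = round(100 * n1 / background, 2),
                 pct_component2 = round(100 * n2 / background, 2),
                 pct_union = round(100 * union_n / background, 2))
}

# run `expr` under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
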