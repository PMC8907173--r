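# Mixed-model residualization for twin cohorts.
#
# The only random effect is an intercept shared by the (at most two) members
# of a family, so the marginal covariance V = R + sigma_b^2 * Z Z' is block
# diagonal with 1x1 and 2x2 blocks. All GLS algebra below exploits that:
# V^{-1} is formed in closed form per block, which makes per-column fits
# cheap enough to run over thousands of genotype columns and microbial
# features. Variance components are moment estimates (within-pair residual
# covariance), iterated with the GLS fit; a dense mixed-model-equation solve
# is kept in the test suite as the independent oracle.

pair_index <- function(family_id) {
  fam <- as.character(family_id)
  idx <- split(seq_along(fam), fam)
  sizes <- lengths(idx)
  if (any(sizes > 2)) stop("families must have at most 2 members")
  pairs <- do.call(rbind, idx[sizes == 2L])
  list(singles = unlist(idx[sizes == 1L], use.names = FALSE),
       p1 = if (is.null(pairs)) integer(0) else pairs[, 1L],
       p2 = if (is.null(pairs)) integer(0) else pairs[, 2L])
}

# multiply V^{-1} by each column of M, for V with pair-block structure
vinv_mult <- function(M, w, pidx, sb2, se2) {
  M <- as.matrix(M)
  out <- matrix(0, nrow(M), ncol(M))
  r <- se2 / w   # residual variances
  if (length(pidx$singles) > 0) {
    s <- pidx$singles
    out[s, ] <- M[s, , drop = FALSE] / (r[s] + sb2)
  }
  if (length(pidx$p1) > 0) {
    i <- pidx$p1; j <- pidx$p2
    a <- r[i] + sb2; d <- r[j] + sb2; b <- sb2
    det <- a * d - b^2
    out[i, ] <- (d * M[i, , drop = FALSE] - b * M[j, , drop = FALSE]) / det
    out[j, ] <- (a * M[j, , drop = FALSE] - b * M[i, , drop = FALSE]) / det
  }
  out
}

# GLS fit of y on X with Var(eps_i) = se2 / w_i plus family intercepts.
# Returns fixed-effect fit, BLUPs, and conditional residuals.
gls_fit <- function(X, y, w, pidx, sb2, se2) {
  VinvX <- vinv_mult(X, w, pidx, sb2, se2)
  XtVX <- crossprod(X, VinvX)
  beta <- solve_sym(XtVX, crossprod(VinvX, y))
  marginal <- y - drop(X %*% beta)
  Vinvm <- drop(vinv_mult(marginal, w, pidx, sb2, se2))
  blup <- numeric(length(y))
  if (sb2 > 0 && length(pidx$p1) > 0) {
    i <- pidx$p1; j <- pidx$p2
    fam_sum <- Vinvm[i] + Vinvm[j]
    blup[i] <- sb2 * fam_sum
    blup[j] <- sb2 * fam_sum
  }
  if (sb2 > 0 && length(pidx$singles) > 0) {
    s <- pidx$singles
    blup[s] <- sb2 * Vinvm[s]
  }
  list(beta = drop(beta),
       fitted = drop(X %*% beta) + blup,
       blup = blup,
       marginal = marginal,
       cond_resid = marginal - blup)
}

# moment estimates of (sigma_b^2, sigma_e^2) from residuals r with weights w
estimate_vc <- function(r, w, pidx) {
  sb2 <- 0
  if (length(pidx$p1) > 0) {
    sb2 <- max(0, mean(r[pidx$p1] * r[pidx$p2]))
  }
  se2 <- mean(w * (r^2 - sb2))
  se2 <- max(se2, 1e-10, 1e-8 * sb2)
  c(sb2 = sb2, se2 = se2)
}

# symmetric solve with an eigen-based pseudo-inverse fallback, so
# rank-deficient fixed-effect designs (constant or aliased covariates)
# yield the minimum-norm coefficient instead of an error
solve_sym <- function(A, b) {
  out <- tryCatch(solve(A, b), error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen(A, symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * 1e-10
  if (!any(keep)) return(matrix(0, nrow(A), ncol(b)))
  e$vectors[, keep, drop = FALSE] %*%
    (crossprod(e$vectors[, keep, drop = FALSE], b) / e$values[keep])
}

# one weighted-least-squares pass used to seed the variance components
wls_resid <- function(X, y, w) {
  fit <- stats::lm.wfit(X, y, w)
  fit$residuals
}

lmm_fit_column <- function(X, y, w, pidx, n_vc_iter = 2L) {
  r <- wls_resid(X, y, w)
  vc <- estimate_vc(r, w, pidx)
  fit <- NULL
  for (it in seq_len(n_vc_iter)) {
    fit <- gls_fit(X, y, w, pidx, vc["sb2"], vc["se2"])
    vc <- estimate_vc(fit$marginal, w, pidx)
  }
  gls_fit(X, y, w, pidx, vc["sb2"], vc["se2"])
}

#' Residualize coded genotypes against covariates and twin relatedness
#'
#' Per coded column, fits a Gaussian linear mixed model with fixed effects
#' from [build_design()] (intercept, age, BMI, shipment dummies, ancestry
#' PCs) and a random intercept per twin pair, and returns the conditional
#' residuals (observed minus fixed effects minus family BLUP), centered.
#' Samples with no co-twin simply contribute no pair information. The
#' column-to-locus group map is carried through for the group lasso.
#'
#' @param x A `coded_genotypes` matrix (or any numeric samples x columns
#'   matrix) with row names matching `cov$sample_id`.
#' @param cov A covariate table (see [validate_covariates()]).
#' @return A `residual_matrix`: samples x columns, `source = "genotype"`,
#'   with the `groups` attribute preserved.
#' @export
gaussian_lmm_residuals <- function(x, cov) {
  cov <- validate_covariates(cov)
  xm <- unclass(x)
  cov <- cov[match(rownames(xm), cov$sample_id), ]
  if (anyNA(cov$sample_id)) stop("covariates missing for some samples")
  X <- build_design(cov)
  pidx <- pair_index(cov$family_id)
  w <- rep(1, nrow(xm))
  res <- matrix(0, nrow(xm), ncol(xm),
                dimnames = dimnames(xm))
  for (j in seq_len(ncol(xm))) {
    fit <- lmm_fit_column(X, xm[, j], w, pidx)
    res[, j] <- fit$cond_resid
  }
  res <- sweep(res, 2L, colMeans(res))
  structure(res, source = "genotype", groups = attr(x, "groups"),
            exclusions = character(0),
            class = c("residual_matrix", "matrix", "array"))
}

#' Residualize Tweedie abundances against covariates and twin relatedness
#'
#' Per microbial feature, fits a Tweedie generalized linear mixed model with
#' log link: fixed effects from [build_design()] and a random intercept per
#' twin pair, estimated by penalized quasi-likelihood (an IRLS loop whose
#' working-response step is the pair-block GLS of the Gaussian path). The
#' global power `p` comes from [estimate_taylor_power()]; the dispersion is
#' absorbed into the per-feature residual variance component, i.e.
#' re-estimated per feature. Returns Pearson residuals
#' `(y - mu) / mu^(p/2)` with `mu` conditional on the family effect,
#' centered per feature.
#'
#' Features whose mixed fit fails to converge fall back to a fixed
#' family-intercept Tweedie GLM; features failing both are dropped and
#' recorded in the `exclusions` attribute. With all-distinct family ids the
#' fit reduces to an ordinary Tweedie GLM.
#'
#' @param table A [feature_table()] of normalized abundances
#'   (features x samples; all features should already pass the prevalence
#'   filter).
#' @param cov Covariate table; rows matched to table columns by `sample_id`.
#' @param p Tweedie power in (1, 2).
#' @param max_iter,tol IRLS controls (default 100 iterations, relative
#'   deviance change below 1e-8).
#' @param type Residual type: `"pearson"` (default; variance-standardized,
#'   the natural input for a correlation analysis), `"response"`
#'   (`y - mu`), or `"deviance"` (signed square-root unit deviance).
#' @return A `residual_matrix`: samples x features, `source = "abundance"`.
#' @export
tweedie_glmm_residuals <- function(table, cov, p, max_iter = 100,
                                   tol = 1e-8,
                                   type = c("pearson", "response",
                                            "deviance")) {
  type <- match.arg(type)
  check_tweedie_params(1, 1, p)
  cov <- validate_covariates(cov)
  vals <- unclass(table)
  cov <- cov[match(colnames(vals), cov$sample_id), ]
  if (anyNA(cov$sample_id)) stop("covariates missing for some samples")
  X <- build_design(cov)
  pidx <- pair_index(cov$family_id)
  fam <- factor(cov$family_id)
  res <- matrix(NA_real_, ncol(vals), nrow(vals),
                dimnames = list(colnames(vals), rownames(vals)))
  dropped <- character(0)
  for (i in seq_len(nrow(vals))) {
    y <- vals[i, ]
    if (all(y == 0)) stop("all-zero feature '", rownames(vals)[i],
                          "'; apply prevalence_filter() first")
    fit <- tweedie_pql(X, y, p, pidx, max_iter = max_iter, tol = tol)
    if (is.null(fit)) {
      fit <- tweedie_fixed_family_glm(X, y, p, fam)
    }
    if (is.null(fit)) {
      dropped <- c(dropped, rownames(vals)[i])
      next
    }
    res[, i] <- switch(type,
      pearson = (y - fit$mu) / fit$mu^(p / 2),
      response = y - fit$mu,
      deviance = {
        d <- 2 * (pmax(y, 0)^(2 - p) / ((1 - p) * (2 - p)) -
                    y * fit$mu^(1 - p) / (1 - p) +
                    fit$mu^(2 - p) / (2 - p))
        sign(y - fit$mu) * sqrt(pmax(d, 0))
      })
  }
  if (length(dropped) > 0) {
    warning(length(dropped), " features dropped for non-convergence")
    res <- res[, !(colnames(res) %in% dropped), drop = FALSE]
  }
  res <- sweep(res, 2L, colMeans(res))
  structure(res, source = "abundance", exclusions = dropped,
            class = c("residual_matrix", "matrix", "array"))
}

tweedie_deviance <- function(y, mu, p) {
  sum(2 * (pmax(y, 0)^(2 - p) / ((1 - p) * (2 - p)) -
             y * mu^(1 - p) / (1 - p) +
             mu^(2 - p) / (2 - p)))
}

# PQL loop: returns list(mu, eta, beta) or NULL on non-convergence.
# Warm-started from a fixed-effects-only Tweedie GLM; the moment variance
# components are damped and frozen after a burn-in so the inner IRLS can
# converge against a fixed marginal covariance.
tweedie_pql <- function(X, y, p, pidx, max_iter = 100, tol = 1e-8,
                        vc_freeze = 10L) {
  start <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = tweedie_family(p),
                                    control = list(maxit = 50))),
    error = function(e) NULL)
  if (!is.null(start) && all(is.finite(start$fitted.values)) &&
      all(start$fitted.values > 0)) {
    mu <- start$fitted.values
  } else {
    mu <- pmax(y, 0.1 * mean(y))
  }
  eta <- log(mu)
  dev <- tweedie_deviance(y, mu, p)
  vc <- NULL
  fit <- NULL
  for (it in seq_len(max_iter)) {
    w <- mu^(2 - p)                 # (dmu/deta)^2 / V(mu) for log link
    z <- eta + (y - mu) / mu
    if (is.null(vc)) {
      vc <- estimate_vc(wls_resid(X, z, w), w, pidx)
    } else if (it <= vc_freeze) {
      vc_new <- estimate_vc(fit$marginal, w, pidx)
      vc <- 0.5 * vc + 0.5 * vc_new
    }
    fit_try <- tryCatch(gls_fit(X, z, w, pidx, vc["sb2"], vc["se2"]),
                        error = function(e) NULL)
    if (is.null(fit_try)) return(NULL)
    fit <- fit_try
    eta_new <- fit$fitted
    # step-halving if the deviance would increase
    step <- 1
    dev_cand <- dev
    repeat {
      eta_cand <- eta + step * (eta_new - eta)
      mu_cand <- exp(pmin(eta_cand, 700))
      dev_cand <- tweedie_deviance(y, mu_cand, p)
      if (is.finite(dev_cand) && dev_cand <= dev + 1e-12 * abs(dev)) break
      step <- step / 2
      if (step < 1 / 64) break
    }
    rel <- abs(dev - dev_cand) / (abs(dev) + 0.1)
    eta <- eta + step * (eta_new - eta)
    mu <- exp(pmin(eta, 700))
    dev <- tweedie_deviance(y, mu, p)
    if (it > 1L && rel < tol) {
      return(list(mu = mu, eta = eta, beta = fit$beta, iterations = it))
    }
  }
  NULL
}

# fallback: fixed family intercepts, plain Tweedie GLM (dummies only when
# some family actually has two members; all-singleton cohorts would be
# saturated by them)
tweedie_fixed_family_glm <- function(X, y, p, fam) {
  Xf <- X
  if (nlevels(fam) > 1L && max(table(fam)) >= 2L) {
    fd <- stats::model.matrix(~fam)[, -1L, drop = FALSE]
    Xf <- cbind(X, fd)
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(Xf, y, family = tweedie_family(p),
                                    control = list(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  list(mu = fit$fitted.values, eta = log(fit$fitted.values),
       beta = fit$coefficients, iterations = fit$iter)
}

#' Write a residual matrix as TSV with a provenance header
#'
#' @param x A `residual_matrix`.
#' @param path Output path.
#' @export
write_residual_matrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# source: %s residuals, centered per column",
                     attr(x, "source")), con)
  excl <- attr(x, "exclusions")
  if (length(excl) > 0) {
    writeLines(paste0("# excluded: ", paste(excl, collapse = ",")), con)
  }
  writeLines(paste(c("sample_id", colnames(x)), collapse = "\t"), con)
  utils::write.table(data.frame(sample_id = rownames(x), unclass(x),
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat(sprintf("<residual_matrix> %d samples x %d columns [%s]%s\n",
              nrow(x), ncol(x), attr(x, "source"),
              if (length(attr(x, "exclusions")) > 0)
                sprintf(", %d excluded", length(attr(x, "exclusions")))
              else ""))
  invisible(x)
}
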