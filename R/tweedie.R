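#' Tweedie probability of a zero observation
#'
#' For a Tweedie compound Poisson-gamma variable with mean `mu`, dispersion
#' `phi` and power `p` in (1, 2), the point mass at zero is
#' `exp(-mu^(2 - p) / (phi * (2 - p)))` — the probability that the underlying
#' Poisson number of gamma jumps is zero. For fixed `phi` and `p` the zero
#' probability decreases as the mean grows, matching the observation that
#' abundant gene families are rarely absent from a sample.
#'
#' @param mu Mean, strictly positive (vectorized).
#' @param phi Dispersion, strictly positive.
#' @param p Power parameter; must lie strictly inside (1, 2). Outside that
#'   range the distribution has no point mass at zero and the formula does
#'   not apply.
#' @return Zero probability in (0, 1), vectorized over `mu`.
#' @export
#' @examples
#' tweedie_zero_probability(1, 1, 1.5) # exp(-2)
tweedie_zero_probability <- function(mu, phi, p) {
  check_tweedie_params(mu, phi, p)
  exp(-mu^(2 - p) / (phi * (2 - p)))
}

check_tweedie_params <- function(mu, phi, p) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("`mu` must be > 0")
  if (!is.finite(phi) || phi <= 0) stop("`phi` must be > 0")
  if (!is.finite(p) || p <= 1 || p >= 2) {
    stop("`p` must lie strictly in (1, 2); for p outside this range the ",
         "Tweedie distribution has no zero mass and is not appropriate ",
         "for zero-inflated abundances")
  }
  invisible(TRUE)
}

#' Draw Tweedie compound Poisson-gamma variates
#'
#' Simulates `Y = sum of N gamma jumps`, where
#' `N ~ Poisson(lambda)` with `lambda = mu^(2-p) / (phi * (2-p))`, and each
#' jump is gamma with shape `(2-p)/(p-1)` and scale `phi * (p-1) * mu^(p-1)`.
#' `N = 0` yields an exact zero, so `P(Y = 0)` equals
#' [tweedie_zero_probability()]. The resulting variable has mean `mu` and
#' variance `phi * mu^p`.
#'
#' Randomness flows through R's global RNG stream; seed with [set.seed()].
#'
#' @param n Number of draws.
#' @param mu Mean (scalar or length-`n` vector), > 0.
#' @param phi Dispersion, > 0.
#' @param p Power in (1, 2).
#' @return Numeric vector of `n` nonnegative draws.
#' @export
sample_tweedie <- function(n, mu, phi, p) {
  check_tweedie_params(mu, phi, p)
  mu <- rep_len(mu, n)
  lambda <- mu^(2 - p) / (phi * (2 - p))
  shape1 <- (2 - p) / (p - 1)
  scale1 <- phi * (p - 1) * mu^(p - 1)
  nj <- stats::rpois(n, lambda)
  y <- numeric(n)
  pos <- nj > 0L
  if (any(pos)) {
    y[pos] <- stats::rgamma(sum(pos), shape = nj[pos] * shape1,
                            scale = scale1[pos])
  }
  y
}

#' Estimate the Tweedie power from the mean-variance power law
#'
#' Across microbial features, the empirical variance scales with the mean as
#' `Var = phi * mean^p` (Taylor's law); on log-log axes this is a straight
#' line whose slope estimates the Tweedie power `p` and whose intercept
#' estimates `log(phi)`. The fit is an ordinary least-squares regression of
#' `log(variance)` on `log(mean)` over the features with strictly positive
#' mean and variance; features failing that are excluded and counted, not
#' imputed. A single global (p, phi) is fitted per table; per-feature
#' dispersion is left to the downstream GLM stage.
#'
#' @param table A [feature_table()] of (normalized) abundances.
#' @return A `tweedie_fit` object with elements `p`, `phi`, `slope_se`,
#'   `intercept_se`, `n_features_used`, `n_features_excluded`, and the
#'   per-feature `log_mean` / `log_var` used.
#' @export
estimate_taylor_power <- function(table) {
  stopifnot(inherits(table, "feature_table") || is.matrix(table))
  vals <- unclass(table)
  mu <- rowMeans(vals)
  v <- apply(vals, 1L, stats::var)
  ok <- is.finite(mu) & is.finite(v) & mu > 0 & v > 0
  if (sum(ok) < 3L) {
    stop("need at least 3 features with positive mean and variance ",
         "to fit the mean-variance power law")
  }
  lx <- log(mu[ok])
  ly <- log(v[ok])
  fit <- stats::lm(ly ~ lx)
  cf <- summary(fit)$coefficients
  structure(list(p = unname(cf["lx", "Estimate"]),
                 phi = exp(unname(cf["(Intercept)", "Estimate"])),
                 slope_se = unname(cf["lx", "Std. Error"]),
                 intercept_se = unname(cf["(Intercept)", "Std. Error"]),
                 n_features_used = sum(ok),
                 n_features_excluded = sum(!ok),
                 log_mean = lx, log_var = ly),
            class = "tweedie_fit")
}

#' @export
print.tweedie_fit <- function(x, ...) {
  cat(sprintf(paste0("Tweedie mean-variance fit: Var(Y) = phi * mu^p\n",
                     "  p   = %.4f (se %.4f)\n",
                     "  phi = %.4f (log-scale se %.4f)\n",
                     "  %d features used, %d excluded\n"),
              x$p, x$slope_se, x$phi, x$intercept_se,
              x$n_features_used, x$n_features_excluded))
  invisible(x)
}

#' @export
glance.tweedie_fit <- function(x, ...) {
  tibble::tibble(p = x$p, phi = x$phi, slope_se = x$slope_se,
                 intercept_se = x$intercept_se,
                 n_features_used = x$n_features_used,
                 n_features_excluded = x$n_features_excluded)
}

#' @export
tidy.tweedie_fit <- function(x, ...) {
  tibble::tibble(term = c("log_mean_slope_p", "intercept_log_phi"),
                 estimate = c(x$p, log(x$phi)),
                 std.error = c(x$slope_se, x$intercept_se))
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.tweedie_fit <- function(object, ...) {
  df <- tibble::tibble(log_mean = object$log_mean, log_var = object$log_var)
  ggplot2::ggplot(df, ggplot2::aes(.data$log_mean, .data$log_var)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(intercept = log(object$phi), slope = object$p,
                         colour = "goldenrod", linewidth = 1) +
    ggplot2::labs(x = "log mean abundance", y = "log variance",
                  title = sprintf("Taylor's law fit: p = %.2f, phi = %.2f",
                                  object$p, object$phi))
}

#' Observed vs expected zero proportions per feature
#'
#' For each feature, compares the observed fraction of zero entries with the
#' zero probability implied by the fitted Tweedie parameters at the feature's
#' mean abundance. When the Tweedie model is adequate the two lie on the
#' diagonal.
#'
#' @param table A [feature_table()].
#' @param fit A `tweedie_fit` with `1 < p < 2`.
#' @return A tibble (`feature_id`, `mean`, `expected_zero`, `observed_zero`),
#'   with an `autoplot()` method.
#' @export
zero_diagnostic <- function(table, fit) {
  stopifnot(inherits(fit, "tweedie_fit"))
  check_tweedie_params(1, fit$phi, fit$p)
  vals <- unclass(table)
  mu <- rowMeans(vals)
  keep <- mu > 0
  out <- tibble::tibble(
    feature_id = rownames(vals)[keep],
    mean = mu[keep],
    expected_zero = tweedie_zero_probability(mu[keep], fit$phi, fit$p),
    observed_zero = rowMeans(vals[keep, , drop = FALSE] == 0))
  class(out) <- c("zero_diagnostic", class(out))
  out
}

#' @export
autoplot.zero_diagnostic <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$expected_zero, .data$observed_zero)) +
    ggplot2::geom_abline(colour = "grey50", linetype = 2) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "expected zero proportion (Tweedie)",
                  y = "observed zero proportion")
}

#' Tweedie family for use with stats::glm
#'
#' Quasi-likelihood family with log link and variance function `mu^p`,
#' suitable for fitting Tweedie generalized linear models with [stats::glm()]
#' for a fixed power `p`. The deviance uses the closed-form Tweedie unit
#' deviance, valid at `y = 0` for `1 < p < 2`.
#'
#' @param p Tweedie power in (1, 2).
#' @return A [stats::family()] object.
#' @export
tweedie_family <- function(p) {
  if (!is.finite(p) || p <= 1 || p >= 2) stop("`p` must be in (1, 2)")
  fam <- stats::poisson(link = "log")
  fam$family <- sprintf("tweedie(p = %.3f)", p)
  fam$variance <- function(mu) mu^p
  fam$dev.resids <- function(y, mu, wt) {
    2 * wt * (pmax(y, 0)^(2 - p) / ((1 - p) * (2 - p)) -
                y * mu^(1 - p) / (1 - p) +
                mu^(2 - p) / (2 - p))
  }
  fam$aic <- function(y, n, mu, wt, dev) NA_real_
  fam$initialize <- expression({
    n <- rep.int(1, nobs)
    if (any(y < 0)) stop("negative values not allowed for the Tweedie family")
    mustart <- pmax(y, 0.1 * max(mean(y), .Machine$double.eps))
  })
  fam$simulate <- NULL
  fam
}
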