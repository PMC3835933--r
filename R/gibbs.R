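#' MCMC configuration
#'
#' Defaults follow common practice for this near-conjugate model: 25 000
#' iterations with a thinning interval of 3 to reduce autocorrelation between
#' stored draws, and a 5 000-iteration (20 percent) burn-in discarded before
#' thinning.
#'
#' @param n_iter Total Gibbs iterations (> `burn_in`).
#' @param thin Thinning interval (>= 1).
#' @param burn_in Initial iterations discarded (>= 0).
#' @param seed Integer RNG seed; identical seed, data and config give
#'   bitwise-identical draws.
#' @return An object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_iter = 25000L, thin = 3L, burn_in = 5000L, seed = 1L) {
  n_iter <- as.integer(n_iter); thin <- as.integer(thin)
  burn_in <- as.integer(burn_in); seed <- as.integer(seed)
  if (is.na(n_iter) || is.na(thin) || is.na(burn_in) || is.na(seed)) {
    stop("mcmc_config fields must be integer-valued", call. = FALSE)
  }
  if (burn_in < 0L || n_iter <= burn_in) {
    stop("need n_iter > burn_in >= 0 (got n_iter = ", n_iter,
         ", burn_in = ", burn_in, ")", call. = FALSE)
  }
  if (thin < 1L) stop("thin must be >= 1", call. = FALSE)
  structure(list(n_iter = n_iter, thin = thin, burn_in = burn_in, seed = seed),
            class = "mcmc_config")
}

# Cholesky-based draw from N(mean, cov); errors if cov is not PD.
.rmvn2 <- function(mean, cov) {
  R <- tryCatch(chol(cov), error = function(e) {
    stop("conditional covariance of (alpha, b) is not positive definite",
         call. = FALSE)
  })
  as.numeric(mean + t(R) %*% stats::rnorm(2L))
}

#' Gibbs sampler for the log-linear allometric model
#'
#' Samples the posterior of \eqn{(\alpha, b, \sigma^2)} for
#' \eqn{y_i = \alpha + b x_i + e_i}, \eqn{e_i \sim N(0, \sigma^2)}, under a
#' bivariate-normal prior \eqn{(\alpha, b) \sim N(\mu_b, \Sigma_b)} and the
#' scalar inverse-Wishart prior on \eqn{\sigma^2} (equivalently
#' inverse-gamma(v/2, vV/2)). Both full conditionals are exact:
#' \deqn{(\alpha, b) \mid \sigma^2, y \sim N(A^{-1} m, A^{-1}), \quad
#'   A = \Sigma_b^{-1} + X'X/\sigma^2, \; m = \Sigma_b^{-1}\mu_b + X'y/\sigma^2}
#' with design matrix \eqn{X = [1, x]}, and
#' \deqn{\sigma^2 \mid \alpha, b, y \sim
#'   \mathrm{InvGamma}\big((v + n)/2, (vV + \mathrm{RSS})/2\big).}
#' The chain is initialised at the least-squares solution (fast convergence
#' for this near-conjugate model), the coefficients are updated jointly as a
#' block, burn-in is discarded and the remainder thinned.
#'
#' @param data A [to_log_data()] object (or list with `x`, `y`, `n`).
#' @param prior A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param fixed_sigma2 Optional: hold the residual variance fixed at this
#'   value instead of sampling it (degenerate variance prior). Useful for
#'   validation against the closed-form conjugate posterior of the
#'   coefficients.
#' @return An object of class `"posterior_draws"`: list with numeric vectors
#'   `alpha`, `b`, `sigma2` of length `floor((n_iter - burn_in) / thin)`,
#'   plus `config`, `prior` and `component`.
#' @export
gibbs_sample <- function(data, prior, config = mcmc_config(),
                         fixed_sigma2 = NULL) {
  stopifnot(inherits(prior, "prior_spec"), inherits(config, "mcmc_config"))
  x <- data$x; y <- data$y; n <- length(x)
  if (n < 3L || length(y) != n || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("regression data must have n >= 3 finite (x, y) pairs", call. = FALSE)
  }
  if (!is.null(fixed_sigma2) && (!is.numeric(fixed_sigma2) || fixed_sigma2 <= 0)) {
    stop("fixed_sigma2 must be a positive number", call. = FALSE)
  }

  X <- cbind(1, x)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  Sigma_inv <- solve(prior$Sigma)
  Sigma_inv_mu <- Sigma_inv %*% prior$mu

  # least-squares start
  beta <- as.numeric(solve(XtX, Xty))
  rss0 <- sum((y - X %*% beta)^2)
  sigma2 <- if (is.null(fixed_sigma2)) max(rss0 / max(n - 2L, 1L), 1e-12)
            else fixed_sigma2

  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  alpha_draws <- numeric(n_keep)
  b_draws <- numeric(n_keep)
  sigma2_draws <- numeric(n_keep)

  shape <- (prior$v + n) / 2
  set.seed(config$seed)
  k <- 0L
  for (iter in seq_len(config$n_iter)) {
    # block update of (alpha, b) | sigma2
    A <- Sigma_inv + XtX / sigma2
    cov_beta <- solve(A)
    mean_beta <- cov_beta %*% (Sigma_inv_mu + Xty / sigma2)
    beta <- .rmvn2(mean_beta, cov_beta)

    # sigma2 | alpha, b  ~ InvGamma((v + n)/2, (v V + RSS)/2)
    if (is.null(fixed_sigma2)) {
      rss <- sum((y - X %*% beta)^2)
      sigma2 <- 1 / stats::rgamma(1L, shape = shape,
                                  rate = (prior$v * prior$V + rss) / 2)
    }

    post <- iter - config$burn_in
    if (post > 0L && post %% config$thin == 0L) {
      k <- k + 1L
      alpha_draws[k] <- beta[1L]
      b_draws[k] <- beta[2L]
      sigma2_draws[k] <- sigma2
    }
  }

  structure(list(alpha = alpha_draws[seq_len(k)], b = b_draws[seq_len(k)],
                 sigma2 = sigma2_draws[seq_len(k)], config = config,
                 prior = prior,
                 component = if (!is.null(data$component)) data$component
                             else NA_character_),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws (%d kept): alpha mean %.4f, b mean %.4f, sigma2 mean %.5f\n",
              length(x$alpha), mean(x$alpha), mean(x$b), mean(x$sigma2)))
  cat(sprintf("  prior: %s; n_iter %d, burn-in %d, thin %d, seed %d\n",
              x$prior$kind, x$config$n_iter, x$config$burn_in,
              x$config$thin, x$config$seed))
  invisible(x)
}

#' Fit summary for one component and method
#'
#' Common container for the three estimation routes: point estimates
#' (posterior means for the Bayesian fits, least-squares estimates for MLS)
#' with equal-tailed 95 percent credible or confidence intervals.
#'
#' @param component Component label (or `NA`).
#' @param method One of `"bayes_informative"`, `"bayes_noninformative"`,
#'   `"mls"`.
#' @param alpha_hat,b_hat Point estimates.
#' @param alpha_interval,b_interval Length-2 `c(lower, upper)` bounds.
#' @param sigma2_hat Residual-variance estimate.
#' @param level Interval probability.
#' @return Object of class `"fit_summary"`.
#' @export
fit_summary <- function(component, method, alpha_hat, b_hat,
                        alpha_interval, b_interval, sigma2_hat, level = 0.95) {
  method <- match.arg(method,
                      c("bayes_informative", "bayes_noninformative", "mls"))
  stopifnot(length(alpha_interval) == 2L, length(b_interval) == 2L)
  if (alpha_interval[1] > alpha_interval[2] || b_interval[1] > b_interval[2]) {
    stop("interval lower bound exceeds upper bound", call. = FALSE)
  }
  if (alpha_hat < alpha_interval[1] || alpha_hat > alpha_interval[2] ||
      b_hat < b_interval[1] || b_hat > b_interval[2]) {
    stop("point estimate falls outside its interval", call. = FALSE)
  }
  structure(list(component = component, method = method,
                 alpha_hat = alpha_hat, b_hat = b_hat,
                 alpha_interval = as.numeric(alpha_interval),
                 b_interval = as.numeric(b_interval),
                 sigma2_hat = sigma2_hat, level = level),
            class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, ...) {
  cat(sprintf("Fit [%s, %s] at %.0f%%:\n",
              x$component, x$method, 100 * x$level))
  cat(sprintf("  alpha = %.4f  (%.4f, %.4f)\n",
              x$alpha_hat, x$alpha_interval[1], x$alpha_interval[2]))
  cat(sprintf("  b     = %.4f  (%.4f, %.4f)\n",
              x$b_hat, x$b_interval[1], x$b_interval[2]))
  cat(sprintf("  sigma2 = %.5f\n", x$sigma2_hat))
  invisible(x)
}

#' @export
as.data.frame.fit_summary <- function(x, ...) {
  data.frame(component = x$component, method = x$method,
             alpha = x$alpha_hat,
             alpha_lower = x$alpha_interval[1], alpha_upper = x$alpha_interval[2],
             b = x$b_hat,
             b_lower = x$b_interval[1], b_upper = x$b_interval[2],
             sigma2 = x$sigma2_hat, level = x$level,
             stringsAsFactors = FALSE)
}

#' Coerce a fit summary to allometric parameters
#'
#' @param fit A [fit_summary()].
#' @return An [allometric_params()] with the point estimates and sigma2.
#' @export
as_allometric_params <- function(fit) {
  stopifnot(inherits(fit, "fit_summary"))
  allometric_params(fit$alpha_hat, fit$b_hat, sigma2 = fit$sigma2_hat)
}

#' Summarise posterior draws
#'
#' Point estimate = posterior mean; interval = equal-tailed sample quantiles
#' (default R quantile rule) at \eqn{(1 - \mathrm{level})/2} and
#' \eqn{1 - (1 - \mathrm{level})/2}.
#'
#' @param draws A [gibbs_sample()] result.
#' @param level Interval probability in (0, 1), default 0.95.
#' @param method Method label recorded in the summary.
#' @return A [fit_summary()].
#' @export
summarize_draws <- function(draws, level = 0.95, method = NULL) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (length(draws$alpha) == 0L) stop("empty chain", call. = FALSE)
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  }
  if (is.null(method)) {
    method <- if (draws$prior$kind == "informative") "bayes_informative"
              else "bayes_noninformative"
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  fit_summary(component = draws$component, method = method,
              alpha_hat = mean(draws$alpha), b_hat = mean(draws$b),
              alpha_interval = unname(stats::quantile(draws$alpha, probs)),
              b_interval = unname(stats::quantile(draws$b, probs)),
              sigma2_hat = mean(draws$sigma2), level = level)
}

#' Export posterior draws as CSV
#'
#' Columns: `iteration` (index of the kept draw), `alpha`, `b`, `sigma2`.
#'
#' @param draws A [gibbs_sample()] result.
#' @param path File path.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  utils::write.csv(data.frame(iteration = seq_along(draws$alpha),
                              alpha = draws$alpha, b = draws$b,
                              sigma2 = draws$sigma2),
                   path, row.names = FALSE)
  invisible(path)
}
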