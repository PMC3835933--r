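# Shared fixture builders: everything generated in code, nothing on disk.

# Hand-constructed log-scale regression data for closed-form checks.
make_log_data <- function(x, y, component = "total") {
  structure(list(x = x, y = y, n = length(x), component = component,
                 tree_id = sprintf("t%03d", seq_along(x))),
            class = "log_regression_data")
}

# Wrap plain numeric vectors as a posterior_draws object so summary and
# diagnostic operations can be exercised on chains with known structure.
as_draws <- function(alpha, b = alpha, sigma2 = abs(alpha) + 1,
                     prior = noninformative_prior()) {
  structure(list(alpha = alpha, b = b, sigma2 = sigma2,
                 config = mcmc_config(seed = 1L), prior = prior,
                 component = "total"),
            class = "posterior_draws")
}

# Closed-form conjugate posterior of (alpha, b) with sigma2 known:
# independent oracle for the Gibbs sampler's coefficient updates.
conjugate_posterior <- function(x, y, mu, Sigma, sigma2) {
  X <- cbind(1, x)
  A <- solve(Sigma) + crossprod(X) / sigma2
  V <- solve(A)
  m <- V %*% (solve(Sigma) %*% mu + crossprod(X, y) / sigma2)
  list(mean = as.numeric(m), cov = V)
}

# Literature tables covering all five components, each centred on its own
# true (alpha, b); spread mirrors a realistic compilation of equations.
component_means <- function() {
  list(stem    = c(-3.8205, 0.9270),
       branch  = c(-5.8277, 0.9136),
       foliage = c(-5.4356, 0.8798),
       root    = c(-4.1500, 0.8117),
       total   = c(-2.1133, 0.8197))
}

make_equation_table <- function(n = 32L, seed = 1L,
                                Sigma = matrix(c(0.36, -0.0324,
                                                 -0.0324, 0.0036), 2, 2)) {
  mus <- component_means()
  do.call(rbind, lapply(seq_along(mus), function(i) {
    generate_literature(lit_sim_config(
      n_equations = n, mu_true = mus[[i]], Sigma_true = Sigma,
      component = names(mus)[i], seed = seed + 97L * i))
  }))
}

# Fast MCMC settings for tests whose point is not chain length.
quick_config <- function(seed = 1L) {
  mcmc_config(n_iter = 4000L, thin = 2L, burn_in = 1000L, seed = seed)
}
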