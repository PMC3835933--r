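test_that("mcmc_config enforces iteration and thinning constraints", {
  cfg <- mcmc_config()
  expect_equal(cfg$n_iter, 25000L)
  expect_equal(cfg$thin, 3L)
  expect_equal(cfg$burn_in, 5000L)
  expect_error(mcmc_config(n_iter = 1000, burn_in = 1000), "n_iter > burn_in")
  expect_error(mcmc_config(thin = 0), "thin")
})

test_that("an almost-point-mass prior dominates the posterior", {
  d <- make_log_data(x = c(5, 6, 7, 8, 9), y = c(1, 1.5, 2.2, 2.8, 3.6))
  tight <- prior_spec(c(-4, 0.9), diag(c(1e-10, 1e-10)))
  dr <- gibbs_sample(d, tight, quick_config(seed = 2))
  expect_equal(mean(dr$alpha), -4, tolerance = 1e-3)
  expect_equal(mean(dr$b), 0.9, tolerance = 1e-3)
})

test_that("with sigma2 fixed, draws match the closed-form conjugate posterior", {
  set.seed(41)
  x <- runif(40, 5, 10)
  y <- -3 + 0.85 * x + rnorm(40, 0, 0.2)
  prior <- prior_spec(c(-4, 0.9), matrix(c(0.25, -0.02, -0.02, 0.01), 2, 2))
  dr <- gibbs_sample(make_log_data(x, y), prior,
                     mcmc_config(n_iter = 21000, thin = 1, burn_in = 1000,
                                 seed = 8),
                     fixed_sigma2 = 0.04)
  oracle <- conjugate_posterior(x, y, prior$mu, prior$Sigma, 0.04)
  expect_equal(mean(dr$alpha), oracle$mean[1], tolerance = 0.01)
  expect_equal(mean(dr$b), oracle$mean[2], tolerance = 0.01)
  emp_cov <- cov(cbind(dr$alpha, dr$b))
  expect_equal(unname(emp_cov), unname(oracle$cov), tolerance = 0.08)
  expect_true(all(dr$sigma2 == 0.04))
})

test_that("posterior recovers known parameters from simulated data", {
  set.seed(7)
  x <- runif(200, 5, 10)
  y <- -3 + 0.85 * x + rnorm(200, 0, 0.1)
  dr <- gibbs_sample(make_log_data(x, y), noninformative_prior(),
                     quick_config(seed = 3))
  expect_lt(abs(mean(dr$alpha) - (-3)), 3 * sd(dr$alpha))
  expect_lt(abs(mean(dr$b) - 0.85), 3 * sd(dr$b))
  expect_true(all(dr$sigma2 > 0))
  expect_equal(length(dr$alpha), (4000 - 1000) %/% 2)
})

test_that("same seed, data and config give bitwise-identical chains", {
  d <- make_log_data(x = c(5, 6, 7, 8), y = c(1, 1.6, 2.1, 2.9))
  a <- gibbs_sample(d, noninformative_prior(), quick_config(seed = 99))
  b <- gibbs_sample(d, noninformative_prior(), quick_config(seed = 99))
  expect_identical(a$alpha, b$alpha)
  expect_identical(a$b, b$b)
  expect_identical(a$sigma2, b$sigma2)
  c <- gibbs_sample(d, noninformative_prior(), quick_config(seed = 100))
  expect_false(identical(a$alpha, c$alpha))
})

test_that("posterior mean moves monotonically toward the prior mean as prior precision grows", {
  set.seed(5)
  x <- runif(30, 5, 10)
  y <- -3 + 0.85 * x + rnorm(30, 0, 0.2)
  d <- make_log_data(x, y)
  b_ls <- ols_fit(d)$b_hat
  prior_b <- 1.2  # deliberately away from the data
  scales <- c(1, 0.1, 0.01, 0.001, 0.0001)
  post_b <- vapply(seq_along(scales), function(i) {
    pr <- prior_spec(c(-5, prior_b), diag(c(1, 0.1)) * scales[i])
    mean(gibbs_sample(d, pr, quick_config(seed = 20 + i))$b)
  }, numeric(1))
  # ladder runs from near the least-squares fit to near the prior mean
  gaps <- abs(post_b - prior_b)
  expect_true(all(diff(gaps) < 0))
  expect_lt(abs(post_b[1] - b_ls), abs(post_b[5] - b_ls))
  expect_equal(post_b[5], prior_b, tolerance = 0.01)
})

test_that("summarize_draws uses posterior means and equal-tailed quantiles", {
  const <- as_draws(rep(2.5, 500))
  s <- summarize_draws(const)
  expect_equal(s$alpha_hat, 2.5)
  expect_equal(s$alpha_interval, c(2.5, 2.5))

  chain <- as_draws(as.numeric(1:100))
  s90 <- summarize_draws(chain, level = 0.90)
  # default R quantile rule on 1..100 at probs 0.05 / 0.95
  expect_equal(s90$alpha_interval, c(5.95, 95.05))

  set.seed(11)
  z <- rnorm(1e5)
  sz <- summarize_draws(as_draws(z))
  expect_equal(sz$alpha_hat, 0, tolerance = 0.02)
  expect_equal(sz$alpha_interval, c(-1.96, 1.96), tolerance = 0.05)

  expect_error(summarize_draws(chain, level = 1.2), "level")
})

test_that("method label follows the prior kind", {
  d <- make_log_data(x = c(5, 6, 7, 8), y = c(1, 1.6, 2.1, 2.9))
  dr_non <- gibbs_sample(d, noninformative_prior(), quick_config(seed = 1))
  expect_identical(summarize_draws(dr_non)$method, "bayes_noninformative")
  pr <- prior_spec(c(-4, 0.9), diag(c(0.3, 0.01)))
  dr_inf <- gibbs_sample(d, pr, quick_config(seed = 1))
  expect_identical(summarize_draws(dr_inf)$method, "bayes_informative")
})

test_that("fit_summary rejects inconsistent intervals", {
  expect_error(fit_summary("total", "mls", 0, 1, c(1, -1), c(0, 2), 0.1),
               "lower")
  expect_error(fit_summary("total", "mls", 5, 1, c(-1, 1), c(0, 2), 0.1),
               "outside")
})

test_that("draw archives round-trip as CSV", {
  d <- make_log_data(x = c(5, 6, 7, 8), y = c(1, 1.6, 2.1, 2.9))
  dr <- gibbs_sample(d, noninformative_prior(), quick_config(seed = 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(dr, path)
  back <- read.csv(path)
  expect_equal(back$alpha, dr$alpha, tolerance = 1e-12)
  expect_equal(nrow(back), length(dr$alpha))
})
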