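test_that("fit_bivariate_prior computes sample mean and unbiased covariance", {
  eqs <- data.frame(source_id = 1:3, component = "stem",
                    alpha = c(-3, -4, -5), b = c(0.9, 1.0, 0.8))
  spec <- fit_bivariate_prior(eqs, "stem")
  # hand computation: mean (-4, 0.9); n-1 covariance [[1, 0.05], [0.05, 0.01]]
  expect_equal(unname(spec$mu), c(-4, 0.9))
  expect_equal(unname(spec$Sigma),
               matrix(c(1, 0.05, 0.05, 0.01), 2, 2))
  expect_equal(spec$V, 1)
  expect_equal(spec$v, 0.001)
  expect_identical(spec$kind, "informative")
  expect_identical(attr(spec, "n_equations"), 3L)
})

test_that("degenerate or undersized literature sets are rejected by name", {
  same <- data.frame(source_id = 1:3, component = "root",
                     alpha = -4, b = 0.9)
  expect_error(fit_bivariate_prior(same, "root"), "degenerate.*root")
  collinear <- data.frame(source_id = 1:4, component = "stem",
                          alpha = c(-3, -4, -5, -6),
                          b = 0.9 + 0.1 * c(-3, -4, -5, -6))
  expect_error(fit_bivariate_prior(collinear, "stem"), "collinear")
  two <- data.frame(source_id = 1:2, component = "stem",
                    alpha = c(-3, -4), b = c(0.9, 1.0))
  expect_error(fit_bivariate_prior(two, "stem"), "at least 3")
})

test_that("elicited mean is invariant to record order and set duplication", {
  eqs <- generate_literature(lit_sim_config(n_equations = 20, seed = 3))
  base <- fit_bivariate_prior(eqs, "stem")
  shuffled <- eqs[sample.int(nrow(eqs)), ]
  expect_equal(fit_bivariate_prior(shuffled, "stem")$mu, base$mu)
  expect_equal(fit_bivariate_prior(shuffled, "stem")$Sigma, base$Sigma)
  doubled <- rbind(eqs, eqs)
  expect_equal(fit_bivariate_prior(doubled, "stem")$mu, base$mu)
})

test_that("elicited covariance is symmetric positive definite on random sets", {
  for (seed in 1:5) {
    eqs <- generate_literature(lit_sim_config(n_equations = 10, seed = seed))
    S <- fit_bivariate_prior(eqs, "stem")$Sigma
    expect_equal(S[1, 2], S[2, 1])
    expect_true(min(eigen(S, symmetric = TRUE)$values) > 0)
  }
})

test_that("non-informative prior is the near-flat N(0, 1000) pair", {
  spec <- noninformative_prior()
  expect_equal(unname(spec$mu), c(0, 0))
  expect_equal(unname(spec$Sigma), diag(c(1000, 1000)))
  expect_identical(spec$kind, "non_informative")
  expect_equal(prior_correlation(spec), 0)
  # near-flat over plausible slopes: density ratio b = 1 vs b = 0
  ratio <- dnorm(1, 0, sqrt(spec$Sigma[2, 2])) /
           dnorm(0, 0, sqrt(spec$Sigma[2, 2]))
  expect_equal(ratio, exp(-1 / 2000))
  expect_gt(ratio, 0.999)
})

test_that("prior_correlation matches hand arithmetic", {
  s1 <- prior_spec(c(0, 0), matrix(c(1, 0.05, 0.05, 0.01), 2, 2))
  expect_equal(prior_correlation(s1), 0.5)
  s2 <- prior_spec(c(0, 0), matrix(c(4, -1, -1, 1), 2, 2))
  expect_equal(prior_correlation(s2), -0.5)
})

test_that("prior_spec validates its covariance and hyperparameters", {
  expect_error(prior_spec(c(0, 0), matrix(c(1, 2, 0.1, 1), 2, 2)), "symmetric")
  expect_error(prior_spec(c(0, 0), matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
  expect_error(prior_spec(c(0, 0), diag(2), V = -1), "positive")
})

test_that("prior JSON and equations CSV round-trip", {
  eqs <- generate_literature(lit_sim_config(n_equations = 8, seed = 4))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_equations(eqs, csv)
  expect_equal(read_equations(csv), eqs, tolerance = 1e-12)

  spec <- fit_bivariate_prior(eqs, "stem")
  js <- withr::local_tempfile(fileext = ".json")
  write_prior(spec, js)
  back <- read_prior(js)
  expect_equal(back$mu, spec$mu)
  expect_equal(back$Sigma, spec$Sigma)
  expect_identical(back$kind, "informative")
})

test_that("moment recovery: large synthetic compilations converge to truth", {
  cfg <- lit_sim_config(n_equations = 1000, mu_true = c(-3.8205, 0.9270),
                        Sigma_true = matrix(c(0.36, -0.9 * 0.6 * 0.06,
                                              -0.9 * 0.6 * 0.06, 0.0036),
                                            2, 2),
                        seed = 12)
  eqs <- generate_literature(cfg)
  spec <- fit_bivariate_prior(eqs, "stem")
  se <- sqrt(diag(cfg$Sigma_true) / cfg$n_equations)
  expect_lt(abs(spec$mu[["alpha"]] - cfg$mu_true[1]), 3 * se[1])
  expect_lt(abs(spec$mu[["b"]] - cfg$mu_true[2]), 3 * se[2])
  expect_lt(abs(prior_correlation(spec) - (-0.9)), 0.05)
})
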