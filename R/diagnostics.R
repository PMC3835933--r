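#' Convergence diagnostics for a posterior chain
#'
#' Reports, per parameter, the autocorrelation-based effective sample size
#' and the Geweke z score comparing the mean of the first 10 percent of the
#' chain against the last 50 percent; |z| > 2 is flagged as evidence the
#' chain has not stabilised. A (near-)constant chain is flagged as
#' degenerate. Both statistics are computed with the standard spectral
#' estimators from the coda package.
#'
#' @param draws A [gibbs_sample()] result with at least 100 kept draws.
#' @return Data frame with columns `parameter`, `ess`, `geweke_z`,
#'   `degenerate`, `flagged`.
#' @export
convergence_diagnostics <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  n <- length(draws$alpha)
  if (n < 100L) {
    stop("chain too short for diagnostics (need >= 100 kept draws, got ",
         n, ")", call. = FALSE)
  }
  chains <- list(alpha = draws$alpha, b = draws$b, sigma2 = draws$sigma2)
  out <- lapply(names(chains), function(p) {
    v <- chains[[p]]
    degenerate <- stats::sd(v) < 1e-12 * max(1, abs(mean(v)))
    if (degenerate) {
      return(data.frame(parameter = p, ess = 1, geweke_z = NA_real_,
                        degenerate = TRUE, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    mc <- coda::mcmc(v)
    ess <- unname(coda::effectiveSize(mc))
    z <- unname(coda::geweke.diag(mc, frac1 = 0.1, frac2 = 0.5)$z)
    data.frame(parameter = p, ess = ess, geweke_z = z,
               degenerate = FALSE,
               flagged = is.finite(z) && abs(z) > 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
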