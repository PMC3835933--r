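#' Prior specification for the allometric coefficients
#'
#' A bivariate-normal prior on \eqn{(\alpha, b)} together with the scalar
#' inverse-Wishart hyperparameters \eqn{(V, v)} of the residual-variance
#' prior. For the 1-dimensional variance the scalar inverse-Wishart(V, v) is
#' the inverse-gamma with shape \eqn{v/2} and scale \eqn{vV/2}, which is how
#' the sampler interprets it.
#'
#' @param mu Length-2 numeric vector of prior means \eqn{(\mu_\alpha, \mu_b)}.
#' @param Sigma 2x2 symmetric positive-definite prior covariance matrix.
#' @param V Inverse-Wishart scale scalar (> 0, default 1).
#' @param v Inverse-Wishart degrees-of-freedom scalar (> 0, default 0.001).
#' @param kind `"informative"` or `"non_informative"`.
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(mu, Sigma, V = 1, v = 0.001,
                       kind = c("informative", "non_informative")) {
  kind <- match.arg(kind)
  mu <- as.numeric(mu)
  Sigma <- as.matrix(Sigma)
  stopifnot(length(mu) == 2L, all(is.finite(mu)),
            all(dim(Sigma) == c(2L, 2L)), all(is.finite(Sigma)))
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma)))) {
    stop("prior covariance Sigma must be symmetric", call. = FALSE)
  }
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("prior covariance Sigma must be positive definite", call. = FALSE)
  }
  if (!is.numeric(V) || V <= 0 || !is.numeric(v) || v <= 0) {
    stop("inverse-Wishart hyperparameters V and v must be positive",
         call. = FALSE)
  }
  dimnames(Sigma) <- list(c("alpha", "b"), c("alpha", "b"))
  structure(list(mu = stats::setNames(mu, c("alpha", "b")), Sigma = Sigma,
                 V = V, v = v, kind = kind),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("%s prior on (alpha, b):\n",
              if (x$kind == "informative") "Informative" else "Non-informative"))
  cat(sprintf("  mu    = (%.4f, %.4f)\n", x$mu[1], x$mu[2]))
  cat(sprintf("  Sigma = [%.5g, %.5g; %.5g, %.5g]  (corr = %.3f)\n",
              x$Sigma[1, 1], x$Sigma[1, 2], x$Sigma[2, 1], x$Sigma[2, 2],
              prior_correlation(x)))
  cat(sprintf("  residual variance ~ scalar inverse-Wishart(V = %g, v = %g)\n",
              x$V, x$v))
  invisible(x)
}

#' Elicit an informative prior from published allometric equations
#'
#' Treats the \eqn{(\alpha, b)} pairs reported by published studies for one
#' biomass component as draws from a bivariate normal and estimates its
#' moments: `mu` is the sample mean and `Sigma` the unbiased (n - 1
#' denominator) sample covariance. All equations are weighted equally. At
#' least three equations are required so the covariance has positive degrees
#' of freedom, and a degenerate (singular) covariance — all pairs identical
#' or collinear — is an error rather than a silently unusable prior.
#'
#' @param equations Data frame with columns `source_id`, `component`,
#'   `alpha`, `b` (see [read_equations()]).
#' @param component One of [biomass_components()].
#' @return A [prior_spec()] with `kind = "informative"`, `V = 1`,
#'   `v = 0.001`, and attribute `"n_equations"`.
#' @export
#' @examples
#' eqs <- data.frame(source_id = 1:3, component = "stem",
#'                   alpha = c(-3, -4, -5), b = c(0.9, 1.0, 0.8))
#' fit_bivariate_prior(eqs, "stem")
fit_bivariate_prior <- function(equations, component) {
  .check_component(component)
  equations <- as.data.frame(equations)
  needed <- c("source_id", "component", "alpha", "b")
  if (!all(needed %in% names(equations))) {
    stop("equations table must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  sub <- equations[equations$component == component, , drop = FALSE]
  if (nrow(sub) < 3L) {
    stop("need at least 3 literature equations for component '", component,
         "' (got ", nrow(sub), ")", call. = FALSE)
  }
  pairs <- cbind(alpha = sub$alpha, b = sub$b)
  if (any(!is.finite(pairs))) {
    stop("non-finite alpha/b in equations for component '", component, "'",
         call. = FALSE)
  }
  mu <- colMeans(pairs)
  Sigma <- stats::var(pairs)  # n - 1 denominator
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev), 1)) {
    stop("degenerate covariance for component '", component,
         "': literature (alpha, b) pairs are identical or collinear",
         call. = FALSE)
  }
  out <- prior_spec(mu = mu, Sigma = Sigma, V = 1, v = 0.001,
                    kind = "informative")
  attr(out, "n_equations") <- nrow(sub)
  out
}

#' Non-informative prior
#'
#' Independent near-flat Gaussian priors \eqn{\alpha \sim N(0, 1000)},
#' \eqn{b \sim N(0, 1000)}, with the same residual-variance hyperparameters
#' (V = 1, v = 0.001) as the informative prior. Over the range of plausible
#' allometric coefficients this prior is essentially flat, so the posterior
#' is dominated by the likelihood.
#'
#' @return A [prior_spec()] with `kind = "non_informative"`.
#' @export
noninformative_prior <- function() {
  prior_spec(mu = c(0, 0), Sigma = diag(c(1000, 1000)),
             V = 1, v = 0.001, kind = "non_informative")
}

#' Prior correlation between the two coefficients
#'
#' @param spec A [prior_spec()].
#' @return The correlation \eqn{\Sigma_{12} / \sqrt{\Sigma_{11}\Sigma_{22}}}
#'   implied by the prior covariance, in \[-1, 1\]. Literature compilations of
#'   allometric equations typically show a strong negative correlation: a
#'   steeper slope is compensated by a lower intercept.
#' @export
prior_correlation <- function(spec) {
  stopifnot(inherits(spec, "prior_spec"))
  spec$Sigma[1, 2] / sqrt(spec$Sigma[1, 1] * spec$Sigma[2, 2])
}

#' Read a literature equations table
#'
#' CSV dialect: header `source_id, component, alpha, b`, one row per
#' published equation of the form ln W = alpha + b ln(D^2 H).
#'
#' @param path File path.
#' @return Data frame with the four columns, component labels validated
#'   against [biomass_components()].
#' @export
read_equations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("source_id", "component", "alpha", "b")
  if (!all(needed %in% names(df))) {
    stop("equations CSV must have header: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  bad <- !df$component %in% biomass_components()
  if (any(bad)) {
    stop("unknown component label(s) in equations CSV: ",
         paste(unique(df$component[bad]), collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_equations
#' @param equations Data frame of equation records.
#' @export
write_equations <- function(equations, path) {
  utils::write.csv(equations, path, row.names = FALSE)
  invisible(path)
}

#' Serialise / deserialise a prior specification as JSON
#'
#' Keys: `mu`, `Sigma` (row-major 2x2), `V`, `v`, `kind`.
#'
#' @param spec A [prior_spec()].
#' @param path File path.
#' @return `write_prior` returns `path` invisibly; `read_prior` the
#'   reconstructed [prior_spec()].
#' @export
write_prior <- function(spec, path) {
  stopifnot(inherits(spec, "prior_spec"))
  jsonlite::write_json(
    list(mu = unname(spec$mu), Sigma = unname(spec$Sigma),
         V = spec$V, v = spec$v, kind = spec$kind),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  Sigma <- if (is.matrix(obj$Sigma)) obj$Sigma else
    matrix(unlist(obj$Sigma), 2, 2, byrow = TRUE)
  prior_spec(mu = obj$mu, Sigma = Sigma, V = obj$V, v = obj$v, kind = obj$kind)
}
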