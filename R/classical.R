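#' Least-squares baseline fit
#'
#' Simple linear regression of ln(W) on ln(D^2 H), the classical counterpart
#' of the Bayesian fits. Intervals are t-based,
#' estimate \eqn{\pm t_{n-2, 1-(1-\mathrm{level})/2} \cdot SE}, appropriate
#' for the small per-cohort samples typical of destructive biomass studies;
#' \eqn{\hat\sigma^2 = RSS / (n - 2)}.
#'
#' @param data A [to_log_data()] object.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A [fit_summary()] with `method = "mls"`.
#' @export
#' @examples
#' d <- structure(list(x = c(0, 1, 2), y = c(0, 2, 2), n = 3L,
#'                     component = "total"),
#'                class = "log_regression_data")
#' ols_fit(d)  # b = 1, alpha = 1/3
ols_fit <- function(data, level = 0.95) {
  x <- data$x; y <- data$y
  if (length(x) < 3L) stop("need n >= 3 observations", call. = FALSE)
  if (stats::sd(x) < 1e-12 * max(1, abs(mean(x)))) {
    stop("singular design: x = ln(D^2 H) is constant", call. = FALSE)
  }
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  est <- stats::coef(fit)
  ci <- stats::confint(fit, level = level)
  rss <- sum(stats::residuals(fit)^2)
  fit_summary(component = if (!is.null(data$component)) data$component
                          else NA_character_,
              method = "mls",
              alpha_hat = unname(est[1]), b_hat = unname(est[2]),
              alpha_interval = unname(ci[1, ]), b_interval = unname(ci[2, ]),
              sigma2_hat = rss / (length(x) - 2L), level = level)
}
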