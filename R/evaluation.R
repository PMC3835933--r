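#' Evaluation statistics on the kilogram scale
#'
#' The three criteria used to compare fitted biomass models, all computed on
#' back-transformed (original-scale) predictions:
#' \deqn{MD = \frac{1}{n}\sum (y_i - \hat y_i), \quad
#'   MAD = \frac{1}{n}\sum |y_i - \hat y_i|, \quad
#'   RMSE = \sqrt{\frac{1}{n}\sum (y_i - \hat y_i)^2}.}
#' Deviations are observed minus predicted, so positive MD means
#' under-prediction. Smaller values indicate a better model. The exact
#' decomposition \eqn{RMSE^2 = MD^2 + \mathrm{var}(y - \hat y)} (population
#' variance, 1/n) holds for every call.
#'
#' @param observed Observed biomass, kg (all > 0).
#' @param predicted Predicted biomass, kg; same length as `observed`.
#' @param component,method Optional labels carried into the result.
#' @return Object of class `"eval_stats"`: list with `component`, `method`,
#'   `MD`, `MAD`, `RMSE`, `n`.
#' @export
#' @examples
#' evaluate(c(10, 20), c(12, 16))  # MD = 1, MAD = 3, RMSE = sqrt(10)
evaluate <- function(observed, predicted,
                     component = NA_character_, method = NA_character_) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (length(observed) < 1L) stop("need at least one observation", call. = FALSE)
  if (any(!is.finite(observed)) || any(observed <= 0)) {
    stop("observed biomass must be positive and finite", call. = FALSE)
  }
  dev <- observed - predicted
  structure(list(component = component, method = method,
                 MD = mean(dev), MAD = mean(abs(dev)),
                 RMSE = sqrt(mean(dev^2)), n = length(dev)),
            class = "eval_stats")
}

#' @export
print.eval_stats <- function(x, ...) {
  cat(sprintf("Evaluation [%s, %s] (n = %d): MD = %.4f, MAD = %.4f, RMSE = %.4f kg\n",
              x$component, x$method, x$n, x$MD, x$MAD, x$RMSE))
  invisible(x)
}

#' @export
as.data.frame.eval_stats <- function(x, ...) {
  data.frame(component = x$component, method = x$method,
             MD = x$MD, MAD = x$MAD, RMSE = x$RMSE, n = x$n,
             stringsAsFactors = FALSE)
}

#' Write an evaluation table as CSV
#'
#' Rows = method, columns = component x criterion, mirroring the
#' conventional layout of biomass-model comparison tables.
#'
#' @param stats_list List of [evaluate()] results.
#' @param path File path.
#' @export
write_eval_table <- function(stats_list, path) {
  long <- do.call(rbind, lapply(stats_list, as.data.frame))
  wide <- stats::reshape(
    long[, c("component", "method", "MD", "MAD", "RMSE")],
    direction = "wide", idvar = "method", timevar = "component")
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Compare component-sum and direct total biomass predictions
#'
#' For each tree, total biomass is predicted two ways: AT, the sum of the
#' four fitted component models (stem + branch + foliage + root), and DT,
#' the directly fitted total-biomass model. When the data-generating process
#' is exactly additive the two should agree closely; divergence indicates
#' either non-additive data or estimation error concentrated in one model.
#'
#' @param component_fits Named list of [fit_summary()] objects with entries
#'   `stem`, `branch`, `foliage`, `root`.
#' @param total_fit A [fit_summary()] for the total model.
#' @param trees Tree table supplying the (D, H) at which to predict.
#' @param correction Passed to [predict_biomass()].
#' @return Object of class `"additivity_report"`: list with `per_tree`
#'   (data frame of tree_id, AT, DT), `correlation` (Pearson AT vs DT),
#'   `mean_bias` (mean of AT - DT, kg) and `relative_bias`
#'   (mean_bias / mean(DT)).
#' @export
additivity_compare <- function(component_fits, total_fit, trees,
                               correction = c("none", "baskerville")) {
  correction <- match.arg(correction)
  comps <- setdiff(biomass_components(), "total")
  missing_fits <- setdiff(comps, names(component_fits))
  if (length(missing_fits) > 0) {
    stop("missing component fit(s): ", paste(missing_fits, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(inherits(total_fit, "fit_summary"))
  if (!inherits(trees, "tree_records")) trees <- as_tree_records(trees)

  D <- trees$D_cm; H <- trees$H_m
  at <- Reduce(`+`, lapply(comps, function(cp) {
    predict_biomass(as_allometric_params(component_fits[[cp]]), D, H,
                    correction = correction)
  }))
  dt <- predict_biomass(as_allometric_params(total_fit), D, H,
                        correction = correction)

  structure(list(
    per_tree = data.frame(tree_id = as.character(trees$tree_id),
                          AT = at, DT = dt, stringsAsFactors = FALSE),
    correlation = stats::cor(at, dt),
    mean_bias = mean(at - dt),
    relative_bias = mean(at - dt) / mean(dt)),
    class = "additivity_report")
}

#' @export
print.additivity_report <- function(x, ...) {
  cat(sprintf("Additivity (AT = component sum vs DT = direct total), n = %d trees:\n",
              nrow(x$per_tree)))
  cat(sprintf("  Pearson correlation: %.4f\n", x$correlation))
  cat(sprintf("  mean bias AT - DT:   %.4f kg (%.2f%% of mean DT)\n",
              x$mean_bias, 100 * x$relative_bias))
  invisible(x)
}
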