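#' Allometric model parameters
#'
#' Bundles the log-scale intercept \eqn{\alpha}, slope \eqn{b} and (optionally)
#' the residual variance \eqn{\sigma^2} of the model
#' \eqn{\ln W = \alpha + b \ln(D^2 H) + e}.
#'
#' @param alpha Log-scale intercept (for W in kg).
#' @param b Log-scale slope on \eqn{\ln(D^2 H)}.
#' @param sigma2 Optional residual variance on the log scale; must be > 0
#'   when supplied.
#' @return An object of class `"allometric_params"`.
#' @export
#' @examples
#' allometric_params(-2.1133, 0.8197, sigma2 = 0.04)
allometric_params <- function(alpha, b, sigma2 = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (!is.null(sigma2)) {
    if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
        sigma2 <= 0) {
      stop("sigma2 must be a single positive finite number", call. = FALSE)
    }
  }
  structure(list(alpha = alpha, b = b, sigma2 = sigma2),
            class = "allometric_params")
}

#' @export
print.allometric_params <- function(x, ...) {
  cat(sprintf("Allometric parameters: alpha = %.4f, b = %.4f", x$alpha, x$b))
  if (!is.null(x$sigma2)) cat(sprintf(", sigma2 = %.4f", x$sigma2))
  cat("\n  model: ln W = alpha + b * ln(D^2 H)\n")
  invisible(x)
}

#' Validate a table of tree records
#'
#' Checks a data frame of tree measurements against the package's tree-table
#' contract: columns `tree_id`, `age`, `D_cm`, `H_m` and one `<component>_kg`
#' column per available biomass component (`NA` = missing). `D`, `H` and every
#' recorded biomass must be strictly positive and each tree must carry at
#' least one biomass value. When all four component masses and the total are
#' present for a tree, the total is compared against the component sum; trees
#' violating additivity beyond `additivity_tol` (relative) are flagged in the
#' `"additivity_violations"` attribute but never altered.
#'
#' @param trees Data frame of tree records.
#' @param additivity_tol Relative tolerance for the total-vs-component-sum
#'   check (default 0.01, i.e. 1 percent, a declared measurement tolerance).
#' @return `trees`, classed `"tree_records"`, with attribute
#'   `"additivity_violations"` (character vector of offending `tree_id`s,
#'   possibly empty).
#' @export
as_tree_records <- function(trees, additivity_tol = 0.01) {
  trees <- as.data.frame(trees)
  needed <- c("tree_id", "age", "D_cm", "H_m")
  missing_cols <- setdiff(needed, names(trees))
  if (length(missing_cols) > 0) {
    stop("tree table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  mass_cols <- intersect(.component_column(biomass_components()), names(trees))
  if (length(mass_cols) == 0) {
    stop("tree table has no biomass column (expected at least one of: ",
         paste(.component_column(biomass_components()), collapse = ", "), ")",
         call. = FALSE)
  }
  bad_dh <- !is.finite(trees$D_cm) | trees$D_cm <= 0 |
    !is.finite(trees$H_m) | trees$H_m <= 0
  if (any(bad_dh)) {
    stop("nonpositive or missing D/H for tree(s): ",
         paste(trees$tree_id[bad_dh], collapse = ", "), call. = FALSE)
  }
  mass <- as.matrix(trees[, mass_cols, drop = FALSE])
  if (any(!is.na(mass) & mass <= 0)) {
    bad <- apply(mass, 1L, function(r) any(!is.na(r) & r <= 0))
    stop("nonpositive biomass for tree(s): ",
         paste(trees$tree_id[bad], collapse = ", "), call. = FALSE)
  }
  if (any(rowSums(!is.na(mass)) == 0)) {
    bad <- rowSums(!is.na(mass)) == 0
    stop("no biomass value for tree(s): ",
         paste(trees$tree_id[bad], collapse = ", "), call. = FALSE)
  }

  # additivity check: flag, never fix
  violations <- character(0)
  comp_cols <- .component_column(setdiff(biomass_components(), "total"))
  if (all(c(comp_cols, "total_kg") %in% names(trees))) {
    full <- stats::complete.cases(trees[, c(comp_cols, "total_kg")])
    if (any(full)) {
      csum <- rowSums(trees[full, comp_cols, drop = FALSE])
      rel <- abs(trees$total_kg[full] - csum) / csum
      violations <- as.character(trees$tree_id[full][rel > additivity_tol])
      if (length(violations) > 0) {
        warning("total biomass differs from component sum beyond ",
                additivity_tol * 100, "% for tree(s): ",
                paste(violations, collapse = ", "), call. = FALSE)
      }
    }
  }
  structure(trees,
            class = c("tree_records", "data.frame"),
            additivity_violations = violations)
}

#' Read / write tree tables
#'
#' CSV dialect: header `tree_id, age, D_cm, H_m, stem_kg, branch_kg,
#' foliage_kg, root_kg, total_kg`; an empty cell means the component was not
#' measured.
#'
#' @param path File path.
#' @param trees A validated tree table (see [as_tree_records()]).
#' @param ... Passed on to [as_tree_records()] (e.g. `additivity_tol`).
#' @return `read_trees` returns a validated `tree_records` data frame;
#'   `write_trees` returns `path` invisibly.
#' @export
read_trees <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tree_records(df, ...)
}

#' @rdname read_trees
#' @export
write_trees <- function(trees, path) {
  utils::write.csv(as.data.frame(trees), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Log-scale regression data for one component
#'
#' Transforms tree records to the fitting scale of the allometric model:
#' \eqn{x_i = \ln(D_i^2 H_i)} (D in cm, H in m, exactly as recorded — no unit
#' conversion) and \eqn{y_i = \ln W_i} (W in kg), preserving tree order.
#'
#' @param trees Tree table (data frame; validated via [as_tree_records()] if
#'   not already).
#' @param component One of [biomass_components()].
#' @return An object of class `"log_regression_data"`: list with `x`, `y`,
#'   `n`, `component` and `tree_id`.
#' @export
#' @examples
#' trees <- data.frame(tree_id = "t1", age = 7, D_cm = 10, H_m = 10,
#'                     total_kg = 1)
#' d <- to_log_data(trees, "total")
#' d$x  # ln(10^2 * 10) = ln(1000)
#' d$y  # ln(1) = 0
to_log_data <- function(trees, component) {
  .check_component(component)
  if (!inherits(trees, "tree_records")) trees <- as_tree_records(trees)
  col <- .component_column(component)
  if (!col %in% names(trees)) {
    stop("component '", component, "' not present in tree table ",
         "(no column ", col, ")", call. = FALSE)
  }
  w <- trees[[col]]
  if (anyNA(w)) {
    stop("missing ", component, " biomass for tree(s): ",
         paste(trees$tree_id[is.na(w)], collapse = ", "), call. = FALSE)
  }
  x <- log(trees$D_cm^2 * trees$H_m)
  y <- log(w)
  if (length(x) < 3L) {
    stop("need at least 3 trees to form regression data (got ",
         length(x), ")", call. = FALSE)
  }
  structure(list(x = x, y = y, n = length(x), component = component,
                 tree_id = as.character(trees$tree_id)),
            class = "log_regression_data")
}

#' @export
print.log_regression_data <- function(x, ...) {
  cat(sprintf("Log-scale regression data: n = %d trees, component = %s\n",
              x$n, x$component))
  cat(sprintf("  x = ln(D^2 H) in [%.3f, %.3f]; y = ln(W) in [%.3f, %.3f]\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Predict biomass on the kilogram scale
#'
#' Back-transforms the log-linear model to the measurement scale:
#' \eqn{\hat W = \exp(\alpha + b \ln(D^2 H))}. Because the exponential of an
#' unbiased log-scale mean under-estimates the arithmetic mean, the
#' Baskerville correction multiplies by \eqn{\exp(\sigma^2 / 2)}; the default
#' is no correction, matching how allometric tables are conventionally
#' reported and evaluated.
#'
#' @param params An [allometric_params()] object.
#' @param D Diameter at breast height, cm (vectorised).
#' @param H Total height, m (vectorised, recycled against `D`).
#' @param correction `"none"` (default) or `"baskerville"`; the latter
#'   requires `params$sigma2`.
#' @return Predicted dry biomass in kg.
#' @export
#' @examples
#' p <- allometric_params(-2.1133, 0.8197)
#' predict_biomass(p, D = 10, H = 10)   # about 34.8 kg
predict_biomass <- function(params, D, H, correction = c("none", "baskerville")) {
  stopifnot(inherits(params, "allometric_params"))
  correction <- match.arg(correction)
  if (any(!is.finite(D)) || any(D <= 0) || any(!is.finite(H)) || any(H <= 0)) {
    stop("D and H must be positive and finite", call. = FALSE)
  }
  w <- exp(params$alpha + params$b * log(D^2 * H))
  if (correction == "baskerville") {
    if (is.null(params$sigma2)) {
      stop("Baskerville correction requires sigma2 in the parameter set",
           call. = FALSE)
    }
    w <- w * exp(params$sigma2 / 2)
  }
  w
}
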