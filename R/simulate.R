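#' Default cohort structure for simulated plantation inventories
#'
#' Three age cohorts with the diameter/height envelopes of a typical
#' multi-age Chinese fir plantation study: 9 trees of age 7 (D 5.7-16.3 cm,
#' H 4.9-9.3 m), 14 of age 16 (D 5.6-22.5 cm, H 5.9-14.8 m) and 16 of age 28
#' (D 8.7-28 cm, H 10.3-22.7 m).
#'
#' @return Data frame with columns `age`, `D_min`, `D_max`, `H_min`,
#'   `H_max`, `proportion`.
#' @export
default_cohorts <- function() {
  data.frame(age = c(7L, 16L, 28L),
             D_min = c(5.7, 5.6, 8.7), D_max = c(16.3, 22.5, 28.0),
             H_min = c(4.9, 5.9, 10.3), H_max = c(9.3, 14.8, 22.7),
             proportion = c(9, 14, 16) / 39)
}

#' Default component-level true allometries for simulation
#'
#' Log-scale (alpha, b) for each tree compartment, set to representative
#' literature-level values for Chinese fir, each with residual variance
#' `sigma2` on the log scale (sd 0.2 by default — a realistic spread for
#' destructively sampled component biomass).
#'
#' @param sigma2 Residual variance applied to every component.
#' @return Named list (stem, branch, foliage, root) of lists with `alpha`,
#'   `b`, `sigma2`.
#' @export
default_true_params <- function(sigma2 = 0.04) {
  list(stem    = list(alpha = -3.8205, b = 0.9270, sigma2 = sigma2),
       branch  = list(alpha = -5.8277, b = 0.9136, sigma2 = sigma2),
       foliage = list(alpha = -5.4356, b = 0.8798, sigma2 = sigma2),
       root    = list(alpha = -4.1500, b = 0.8117, sigma2 = sigma2))
}

#' Tree-simulation configuration
#'
#' @param n_trees Number of trees to generate.
#' @param cohorts Data frame as returned by [default_cohorts()]; proportions
#'   must sum to 1 and all ranges be positive and ordered.
#' @param true_params Named list (stem, branch, foliage, root) of lists with
#'   `alpha`, `b`, `sigma2` (>= 0; 0 gives the noiseless limit).
#' @param hd_noise Standard deviation of log-height given log-diameter.
#' @param seed Integer master seed; per-component noise uses sub-streams
#'   derived from it so adding a component does not perturb the others.
#' @return Object of class `"tree_sim_config"`.
#' @export
tree_sim_config <- function(n_trees = 39L, cohorts = default_cohorts(),
                            true_params = default_true_params(),
                            hd_noise = 0.05, seed = 1L) {
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1L) stop("n_trees must be >= 1", call. = FALSE)
  cohorts <- as.data.frame(cohorts)
  needed <- c("age", "D_min", "D_max", "H_min", "H_max", "proportion")
  if (!all(needed %in% names(cohorts))) {
    stop("cohorts must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(cohorts$proportion) - 1) > 1e-8) {
    stop("cohort proportions must sum to 1", call. = FALSE)
  }
  if (any(cohorts$D_min <= 0) || any(cohorts$H_min <= 0) ||
      any(cohorts$D_max < cohorts$D_min) || any(cohorts$H_max < cohorts$H_min)) {
    stop("cohort D/H ranges must be positive and ordered", call. = FALSE)
  }
  comps <- setdiff(biomass_components(), "total")
  if (!all(comps %in% names(true_params))) {
    stop("true_params must name every component: ",
         paste(comps, collapse = ", "), call. = FALSE)
  }
  for (cp in comps) {
    p <- true_params[[cp]]
    if (!all(c("alpha", "b", "sigma2") %in% names(p)) ||
        !is.finite(p$alpha) || !is.finite(p$b) ||
        !is.finite(p$sigma2) || p$sigma2 < 0) {
      stop("invalid true parameters for component '", cp, "'", call. = FALSE)
    }
  }
  if (!is.numeric(hd_noise) || hd_noise < 0) {
    stop("hd_noise must be >= 0", call. = FALSE)
  }
  structure(list(n_trees = n_trees, cohorts = cohorts,
                 true_params = true_params, hd_noise = hd_noise,
                 seed = as.integer(seed)),
            class = "tree_sim_config")
}

# deterministic allocation of n trees across cohorts by proportion
.cohort_counts <- function(n, prop) {
  diff(c(0L, as.integer(round(cumsum(prop) * n))))
}

#' Generate a synthetic tree inventory
#'
#' Emulates a destructively sampled plantation dataset. Within each cohort,
#' diameters are uniform on the cohort D-range; log-height follows the
#' log-linear trend through the cohort's range endpoints plus Gaussian noise
#' (sd `hd_noise`), clipped to the cohort H-range. Each component biomass is
#' \eqn{W = \exp(\alpha + b \ln(D^2 H) + \varepsilon)},
#' \eqn{\varepsilon \sim N(0, \sigma^2)}, and the recorded total is exactly
#' the sum of the four components (additive truth). Deterministic under the
#' configured seed.
#'
#' @param config A [tree_sim_config()].
#' @return A validated `tree_records` data frame.
#' @export
#' @examples
#' trees <- generate_trees(tree_sim_config(n_trees = 10, seed = 42))
#' range(trees$D_cm)
generate_trees <- function(config = tree_sim_config()) {
  stopifnot(inherits(config, "tree_sim_config"))
  co <- config$cohorts
  counts <- .cohort_counts(config$n_trees, co$proportion)

  set.seed(config$seed)
  age <- integer(0); D <- numeric(0); H <- numeric(0)
  for (i in seq_len(nrow(co))) {
    m <- counts[i]
    if (m == 0L) next
    Di <- stats::runif(m, co$D_min[i], co$D_max[i])
    # log-linear H|D trend anchored at the cohort range endpoints
    slope <- (log(co$H_max[i]) - log(co$H_min[i])) /
             (log(co$D_max[i]) - log(co$D_min[i]))
    icpt <- log(co$H_min[i]) - slope * log(co$D_min[i])
    lnH <- icpt + slope * log(Di) + stats::rnorm(m, 0, config$hd_noise)
    Hi <- pmin(pmax(exp(lnH), co$H_min[i]), co$H_max[i])
    age <- c(age, rep(co$age[i], m)); D <- c(D, Di); H <- c(H, Hi)
  }

  x <- log(D^2 * H)
  comps <- setdiff(biomass_components(), "total")
  mass <- matrix(NA_real_, length(D), length(comps),
                 dimnames = list(NULL, comps))
  for (i in seq_along(comps)) {
    p <- config$true_params[[comps[i]]]
    # per-component sub-stream keyed by the component's fixed position
    set.seed((config$seed + 1000L * i) %% .Machine$integer.max)
    eps <- stats::rnorm(length(D), 0, sqrt(p$sigma2))
    mass[, i] <- exp(p$alpha + p$b * x + eps)
  }

  trees <- data.frame(tree_id = sprintf("t%03d", seq_along(D)),
                      age = age, D_cm = D, H_m = H,
                      stem_kg = mass[, "stem"], branch_kg = mass[, "branch"],
                      foliage_kg = mass[, "foliage"], root_kg = mass[, "root"],
                      total_kg = rowSums(mass),
                      stringsAsFactors = FALSE)
  as_tree_records(trees)
}

#' Literature-simulation configuration
#'
#' @param n_equations Number of synthetic published equations.
#' @param mu_true Length-2 true mean of (alpha, b).
#' @param Sigma_true 2x2 positive-definite true covariance; the off-diagonal
#'   must be <= 0, reflecting the negative alpha-b correlation seen in real
#'   compilations of allometric equations.
#' @param component Component label attached to the generated records.
#' @param seed Integer seed.
#' @return Object of class `"lit_sim_config"`.
#' @export
lit_sim_config <- function(n_equations = 32L,
                           mu_true = c(-3.8205, 0.9270),
                           Sigma_true = matrix(c(0.36, -0.9 * 0.6 * 0.06,
                                                 -0.9 * 0.6 * 0.06, 0.0036),
                                               2, 2),
                           component = "stem", seed = 1L) {
  n_equations <- as.integer(n_equations)
  if (is.na(n_equations) || n_equations < 1L) {
    stop("n_equations must be >= 1", call. = FALSE)
  }
  .check_component(component)
  mu_true <- as.numeric(mu_true)
  Sigma_true <- as.matrix(Sigma_true)
  stopifnot(length(mu_true) == 2L, all(dim(Sigma_true) == c(2L, 2L)))
  ev <- eigen((Sigma_true + t(Sigma_true)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma_true must be positive definite", call. = FALSE)
  if (Sigma_true[1, 2] > 0) {
    stop("Sigma_true off-diagonal must be <= 0 (negative alpha-b correlation)",
         call. = FALSE)
  }
  structure(list(n_equations = n_equations, mu_true = mu_true,
                 Sigma_true = Sigma_true, component = component,
                 seed = as.integer(seed)),
            class = "lit_sim_config")
}

#' Generate a synthetic literature equations table
#'
#' Draws (alpha, b) pairs from the configured bivariate normal, emulating a
#' compilation of published allometric equations for one component.
#' Deterministic under the configured seed.
#'
#' @param config A [lit_sim_config()].
#' @return Data frame with columns `source_id`, `component`, `alpha`, `b`.
#' @export
generate_literature <- function(config = lit_sim_config()) {
  stopifnot(inherits(config, "lit_sim_config"))
  set.seed(config$seed)
  draws <- MASS::mvrnorm(config$n_equations, mu = config$mu_true,
                         Sigma = config$Sigma_true)
  draws <- matrix(draws, ncol = 2L)
  data.frame(source_id = sprintf("src%04d", seq_len(config$n_equations)),
             component = config$component,
             alpha = draws[, 1L], b = draws[, 2L],
             stringsAsFactors = FALSE)
}
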