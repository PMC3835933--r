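#' Fit one component by all three methods
#'
#' Runs least squares, Gibbs under the non-informative prior and (when the
#' equations table covers the component) Gibbs under the literature-elicited
#' informative prior, on the same log-scale data. Per-fit RNG seeds are
#' derived deterministically from `config$seed`, the component's position in
#' [biomass_components()] and the method, so the full set of fits is
#' reproducible and fits do not share a stream.
#'
#' @param trees Tree table.
#' @param equations Equations table (or `NULL` to skip the informative fit).
#' @param component One of [biomass_components()].
#' @param config An [mcmc_config()]; its seed is the base seed.
#' @param level Interval probability.
#' @return Named list with elements `mls`, `bayes_noninformative`,
#'   `bayes_informative` ([fit_summary()] or `NULL`), and `draws` (named list
#'   of the two posterior chains actually run).
#' @export
fit_component_models <- function(trees, equations = NULL, component,
                                 config = mcmc_config(), level = 0.95) {
  .check_component(component)
  dat <- to_log_data(trees, component)
  idx <- match(component, biomass_components())

  fits <- list(mls = ols_fit(dat, level = level))
  draws <- list()

  cfg_non <- mcmc_config(config$n_iter, config$thin, config$burn_in,
                         seed = config$seed + 10L * idx + 1L)
  draws$bayes_noninformative <- gibbs_sample(dat, noninformative_prior(), cfg_non)
  fits$bayes_noninformative <- summarize_draws(draws$bayes_noninformative,
                                               level = level)

  fits$bayes_informative <- NULL
  if (!is.null(equations)) {
    if (sum(equations$component == component) >= 3L) {
      prior <- fit_bivariate_prior(equations, component)
      cfg_inf <- mcmc_config(config$n_iter, config$thin, config$burn_in,
                             seed = config$seed + 10L * idx + 2L)
      draws$bayes_informative <- gibbs_sample(dat, prior, cfg_inf)
      fits$bayes_informative <- summarize_draws(draws$bayes_informative,
                                                level = level)
    } else {
      warning("fewer than 3 literature equations for component '", component,
              "'; informative fit skipped", call. = FALSE)
    }
  }
  c(fits, list(draws = draws))
}

#' Run the full estimation pipeline
#'
#' End-to-end workflow: read a tree table and a literature equations table,
#' fit every available biomass component by MLS, non-informative Bayes and
#' informative Bayes, evaluate each fit on the kilogram scale (in-sample, as
#' biomass studies conventionally report), compare component-sum (AT) and
#' direct-total (DT) predictions, and write all results plus a manifest to
#' `out_dir`.
#'
#' Outputs written: `fits.csv` (one row per component x method),
#' `evaluation.csv` (MD/MAD/RMSE wide table), `additivity.csv` and
#' `additivity.json`, per-chain draw archives under `draws/`, and
#' `manifest.json` recording the configuration, seeds and input checksums.
#'
#' @param tree_csv Path to the tree CSV (see [read_trees()]).
#' @param equations_csv Path to the equations CSV (see [read_equations()]),
#'   or `NULL` to skip informative fits.
#' @param out_dir Output directory (created if needed).
#' @param config An [mcmc_config()].
#' @param level Interval probability.
#' @param correction Back-transformation correction used for evaluation and
#'   additivity predictions (`"none"` or `"baskerville"`).
#' @param save_draws Write per-chain CSV archives (default `TRUE`).
#' @param quiet Suppress stage-boundary messages.
#' @return Invisibly, a list with `fits` (data frame), `fit_objects`,
#'   `evaluation` (data frame), `additivity` (report or `NULL`) and
#'   `manifest`.
#' @export
run_pipeline <- function(tree_csv, equations_csv = NULL, out_dir,
                         config = mcmc_config(), level = 0.95,
                         correction = c("none", "baskerville"),
                         save_draws = TRUE, quiet = FALSE) {
  correction <- match.arg(correction)
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(...)

  trees <- read_trees(tree_csv)
  say("read ", nrow(trees), " tree records from ", tree_csv)
  equations <- NULL
  if (!is.null(equations_csv)) {
    equations <- read_equations(equations_csv)
    say("read ", nrow(equations), " literature equations from ", equations_csv)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (save_draws) {
    dir.create(file.path(out_dir, "draws"), showWarnings = FALSE)
  }

  components <- intersect(biomass_components(),
                          sub("_kg$", "", grep("_kg$", names(trees),
                                               value = TRUE)))
  fit_objects <- list()
  eval_stats <- list()
  for (cp in components) {
    say("fitting component '", cp, "' (n = ", nrow(trees), ")")
    res <- fit_component_models(trees, equations, cp,
                                config = config, level = level)
    fit_objects[[cp]] <- res
    obs <- trees[[.component_column(cp)]]
    for (mth in c("mls", "bayes_noninformative", "bayes_informative")) {
      fit <- res[[mth]]
      if (is.null(fit)) next
      pred <- predict_biomass(as_allometric_params(fit), trees$D_cm,
                              trees$H_m, correction = correction)
      eval_stats[[paste(cp, mth, sep = ".")]] <-
        evaluate(obs, pred, component = cp, method = mth)
    }
    if (save_draws) {
      for (mth in names(res$draws)) {
        write_draws(res$draws[[mth]],
                    file.path(out_dir, "draws",
                              paste0(cp, "_", mth, ".csv")))
      }
    }
  }

  fits_df <- do.call(rbind, lapply(fit_objects, function(res) {
    do.call(rbind, lapply(c("mls", "bayes_noninformative",
                            "bayes_informative"), function(m) {
      if (is.null(res[[m]])) NULL else as.data.frame(res[[m]])
    }))
  }))
  rownames(fits_df) <- NULL
  utils::write.csv(fits_df, file.path(out_dir, "fits.csv"), row.names = FALSE)
  write_eval_table(eval_stats, file.path(out_dir, "evaluation.csv"))

  # additivity: prefer the informative fits, fall back to MLS
  additivity <- NULL
  comps4 <- setdiff(biomass_components(), "total")
  if (all(c(comps4, "total") %in% components)) {
    use <- if (all(vapply(c(comps4, "total"), function(cp) {
      !is.null(fit_objects[[cp]]$bayes_informative)
    }, logical(1L)))) "bayes_informative" else "mls"
    additivity <- additivity_compare(
      lapply(stats::setNames(comps4, comps4),
             function(cp) fit_objects[[cp]][[use]]),
      fit_objects$total[[use]], trees, correction = correction)
    utils::write.csv(additivity$per_tree,
                     file.path(out_dir, "additivity.csv"), row.names = FALSE)
    jsonlite::write_json(list(method = use,
                              correlation = additivity$correlation,
                              mean_bias = additivity$mean_bias,
                              relative_bias = additivity$relative_bias),
                         file.path(out_dir, "additivity.json"),
                         auto_unbox = TRUE, digits = NA)
    say("additivity (", use, "): correlation ",
        sprintf("%.4f", additivity$correlation))
  }

  manifest <- list(
    tree_csv = tree_csv, equations_csv = equations_csv,
    tree_md5 = unname(tools::md5sum(tree_csv)),
    equations_md5 = if (is.null(equations_csv)) NULL
                    else unname(tools::md5sum(equations_csv)),
    config = unclass(config), level = level, correction = correction,
    save_draws = save_draws,
    package_version = as.character(utils::packageVersion("allobayes")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("pipeline finished in ",
      sprintf("%.1f", as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      " s; outputs in ", out_dir)

  invisible(list(fits = fits_df, fit_objects = fit_objects,
                 evaluation = do.call(rbind, lapply(eval_stats, as.data.frame)),
                 additivity = additivity, manifest = manifest))
}

#' Re-run a pipeline from its manifest
#'
#' Reads a `manifest.json` written by [run_pipeline()], verifies the input
#' checksums and reproduces the run exactly.
#'
#' @param manifest_path Path to a manifest JSON.
#' @param out_dir Output directory for the re-run.
#' @param quiet Suppress messages.
#' @return As [run_pipeline()].
#' @export
run_from_manifest <- function(manifest_path, out_dir, quiet = FALSE) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!is.null(m$tree_md5) &&
      !identical(unname(tools::md5sum(m$tree_csv)), m$tree_md5)) {
    stop("tree CSV checksum mismatch: ", m$tree_csv, call. = FALSE)
  }
  if (!is.null(m$equations_csv) && !is.null(m$equations_md5) &&
      !identical(unname(tools::md5sum(m$equations_csv)), m$equations_md5)) {
    stop("equations CSV checksum mismatch: ", m$equations_csv, call. = FALSE)
  }
  run_pipeline(m$tree_csv, m$equations_csv, out_dir,
               config = mcmc_config(m$config$n_iter, m$config$thin,
                                    m$config$burn_in, m$config$seed),
               level = m$level, correction = m$correction,
               save_draws = m$save_draws, quiet = quiet)
}
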