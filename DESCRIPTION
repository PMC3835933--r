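Package: allobayes
Title: Bayesian Allometric Tree Biomass Estimation with Literature-Elicited Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the log-linear allometric biomass model ln W = alpha +
    b * ln(D^2 H) to destructively sampled tree data by least squares and
    by a from-scratch Gibbs sampler under two prior specifications: a
    near-flat Gaussian prior and an informative bivariate-normal prior on
    (alpha, b) elicited from a compilation of published allometric
    equations. Provides back-transformed biomass prediction with optional
    Baskerville correction, MD/MAD/RMSE model evaluation on the kilogram
    scale, an additivity comparison of component-sum versus directly
    fitted total biomass, and a synthetic-data generator emulating
    multi-cohort plantation inventories for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
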