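# allobayes

Bayesian estimation of allometric tree-biomass equations, with informative
priors elicited from published literature.

## The problem

Forest carbon accounting and inventory work rest on allometric biomass
equations: power-law relations predicting the dry mass of a tree — per
compartment (stem, branch, foliage, root) and in total — from cheap field
measurements. The workhorse model is

```
ln W = α + b · ln(D²H) + e,    e ~ N(0, σ²)
```

with `W` dry biomass (kg), `D` diameter at breast height (cm), `H` total
height (m). Destructive sampling is expensive, so these equations are
typically fitted to a few dozen trees — small enough that classical least
squares (MLS) leaves wide confidence intervals, and small enough that the
dozens of equations already published for the same species carry real
information. `allobayes` is for forest biometricians who want to use that
information: it compiles published `(α, b)` pairs into a bivariate-normal
prior (their strong negative correlation included), fits the model by a
from-scratch Gibbs sampler under that informative prior, under a near-flat
`N(0, 1000)` prior, and by least squares, and compares the three fits with
mean deviation (MD), mean absolute deviation (MAD) and root mean square
error (RMSE) on back-transformed, kilogram-scale predictions. It also checks
additivity: total biomass predicted by summing the four component models
(AT) against a directly fitted total model (DT).

The Gibbs sampler uses the exact full conditionals of the conjugate
Gaussian model — a joint bivariate-normal update of `(α, b)` and an
inverse-gamma update of `σ²` from the scalar inverse-Wishart prior
(V = 1, v = 0.001) — with 25 000 iterations, 5 000 burn-in and thinning 3 by
default. A synthetic-data generator emulating a three-cohort plantation
inventory (39 trees, ages 7/16/28) makes every stage testable end to end.

## Worked example

```r
library(allobayes)

# a 39-tree, three-cohort inventory and a 32-equation literature compilation
trees <- generate_trees(tree_sim_config(n_trees = 39, seed = 1))
lit   <- generate_literature(lit_sim_config(n_equations = 32, seed = 2))

prior <- fit_bivariate_prior(lit, "stem")
prior
#> Informative prior on (alpha, b):
#>   mu    = (-3.9688, 0.9423)
#>   Sigma = [0.46554, -0.049654; -0.049654, 0.0061672]  (corr = -0.927)
#>   residual variance ~ scalar inverse-Wishart(V = 1, v = 0.001)

d <- to_log_data(trees, "stem")
summarize_draws(gibbs_sample(d, prior, mcmc_config(seed = 3)))
#> Fit [stem, bayes_informative] at 95%:
#>   alpha = -3.8467  (-4.4252, -3.2767)
#>   b     = 0.9307  (0.8595, 1.0026)
#>   sigma2 = 0.06814

ols_fit(d)
#> Fit [stem, mls] at 95%:
#>   alpha = -3.8220  (-4.4714, -3.1727)
#>   b     = 0.9278  (0.8474, 1.0082)
#>   sigma2 = 0.06511
```

The elicited prior shows the expected strong negative α–b correlation
(−0.93 here): literature equations trade intercept against slope. The
informative-prior posterior lands close to least squares on this sample but
with visibly narrower 95% intervals (0.143 vs 0.161 wide for `b`) — the
prior is doing exactly the work it is meant to do at n = 39. On the
kilogram scale:

```r
pred <- predict_biomass(as_allometric_params(
  summarize_draws(gibbs_sample(d, prior, mcmc_config(seed = 3)))),
  trees$D_cm, trees$H_m)
evaluate(trees$stem_kg, pred, "stem", "bayes_informative")
#> Evaluation [stem, bayes_informative] (n = 39): MD = 2.8829, MAD = 12.6869, RMSE = 22.8644 kg
```

Positive MD means under-prediction on average (deviations are observed
minus predicted). `run_pipeline()` runs all five components by all three
methods, writes the fit and evaluation tables, the AT-vs-DT additivity
report, draw archives and a manifest from which the run can be reproduced
exactly (`run_from_manifest()`).

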