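---
title: "Methods: Bayesian allometric biomass estimation with literature-elicited priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian allometric biomass estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`allobayes` fits the log-linear allometric biomass model

$$\ln W_i = \alpha + b \ln(D_i^2 H_i) + e_i, \qquad e_i \sim N(0, \sigma^2),$$

separately for each biomass component (stem, branch, foliage, root) and for
the directly measured total. $W$ is component dry mass in kg, $D$ diameter
at breast height in cm, $H$ total height in m; units are fixed — the package
performs no unit detection or conversion. $D^2H$ is the usual volume-proxy
predictor; taking logarithms linearises the power law and stabilises the
strongly size-dependent variance of biomass data, so a single homoscedastic
$\sigma^2$ on the log scale is assumed. The two-predictor form
$W = aD^bH^c$ is deliberately out of scope.

Back-transformed predictions are $\hat W = \exp(\hat\alpha + \hat b
\ln(D^2H))$. Exponentiating a log-scale mean under-estimates the arithmetic
mean; the Baskerville factor $\exp(\sigma^2/2)$ is available via
`predict_biomass(..., correction = "baskerville")` but the default is
`"none"`, matching how allometric tables are conventionally reported and
evaluated. All evaluation in this package therefore uses uncorrected
predictions unless the caller opts in.

## Priors

Two prior specifications share the residual-variance prior, a scalar
inverse-Wishart with $V = 1$ and $v = 0.001$. For a 1-dimensional variance
this is read, as is standard, as the inverse-gamma with shape $v/2$ and
scale $vV/2$ — an essentially flat prior on $\sigma^2$.

**Non-informative**: independent $\alpha \sim N(0, 1000)$,
$b \sim N(0, 1000)$. Over the plausible range of allometric coefficients
(roughly $\alpha \in (-7, 0)$, $b \in (0, 1.5)$) the density ratio to the
mode is within a fraction of a percent of 1, so the likelihood dominates and
the posterior effectively reproduces least squares.

**Informative**: $(\alpha, b) \sim N_2(\mu_b, \Sigma_b)$ with moments
estimated from a compilation of published equations for the same component,
each publication contributing one $(\alpha, b)$ pair with equal weight
(`fit_bivariate_prior`). $\mu_b$ is the sample mean and $\Sigma_b$ the
unbiased ($n-1$ denominator) sample covariance; with literature sets of a
few dozen equations the choice of denominator is visible, and the unbiased
estimator is the standard one for small samples. At least three equations
are required so the covariance has positive degrees of freedom, and an
exactly singular covariance (identical or collinear pairs) is an error: such
a prior would constrain the posterior to a line. Only equations already in
the $\ln W = \alpha + b\ln(D^2H)$ form are accepted; no meta-regression
weighting by source sample size is attempted. Real compilations show a
strong negative correlation between $\alpha$ and $b$ — a steeper slope is
compensated by a lower intercept — and the elicited $\Sigma_b$ carries that
correlation into the fit.

## Gibbs sampler

The model is conditionally conjugate, so the sampler (`gibbs_sample`)
alternates exact full-conditional draws:

* $(\alpha, b) \mid \sigma^2, y \sim N_2(A^{-1}m, A^{-1})$ with
  $A = \Sigma_b^{-1} + X'X/\sigma^2$ and
  $m = \Sigma_b^{-1}\mu_b + X'y/\sigma^2$, where $X = [1, x]$;
* $\sigma^2 \mid \alpha, b, y \sim \mathrm{InvGamma}\big((v+n)/2,\,
  (vV + \mathrm{RSS})/2\big)$.

Design choices, each made where the procedure was genuinely open:

* **Block update.** $(\alpha, b)$ is drawn jointly (via Cholesky) rather
  than coordinate-wise; this is exact for this model and avoids the slow
  mixing a strong posterior correlation would cause in scalar Gibbs.
* **Initialisation** at the least-squares solution. The posterior is
  unimodal and near-Gaussian, so this starts the chain essentially in the
  typical set.
* **Defaults**: 25 000 iterations, thinning 3. No burn-in length came with
  those settings, so the package discards the first 5 000 iterations (20%) —
  generous for a chain started at the least-squares solution — leaving 6 666
  stored draws. All three are configurable (`mcmc_config`), and identical
  seed + data + config gives bitwise-identical chains.
* **Summaries** (`summarize_draws`): point estimate = posterior mean
  (matching the convention of the GLMM MCMC tooling this workflow descends
  from), intervals = equal-tailed sample quantiles under R's default
  quantile rule. Equal-tailed rather than HPD keeps the Bayesian intervals
  directly comparable with the t-based least-squares confidence intervals;
  for these near-symmetric posteriors the two nearly coincide anyway.

Convergence reporting (`convergence_diagnostics`) is limited to two
standard statistics — spectral effective sample size and the Geweke z score
(first 10% vs last 50%, |z| > 2 flagged) — computed with `coda`. No
multi-chain R-hat machinery is included.

The least-squares baseline (`ols_fit`) is closed-form simple regression via
`stats::lm` with $\hat\sigma^2 = \mathrm{RSS}/(n-2)$ and t-based intervals;
t rather than normal because destructive biomass samples are small (tens of
trees, cohorts down to single digits).

## Evaluation

`evaluate` computes, on the kilogram scale,

$$MD = \tfrac1n\sum(y_i - \hat y_i), \quad
  MAD = \tfrac1n\sum|y_i - \hat y_i|, \quad
  RMSE = \sqrt{\tfrac1n\sum(y_i - \hat y_i)^2},$$

with deviations **observed minus predicted**, so positive MD means
under-prediction. The identity $RMSE^2 = MD^2 + \mathrm{var}(y - \hat y)$
(population variance) holds exactly and is asserted in the tests.
Predictions for evaluation plug the point estimates into the model —
posterior means, not the posterior-predictive mean — mirroring how
single-number parameter estimates feed published evaluation tables.
Evaluation is in-sample on the fitting data by default, as such tables are
conventionally reported; nothing prevents the caller from passing held-out
trees.

`additivity_compare` predicts each tree's total two ways — AT, the sum of
the four component models, and DT, the direct total model — and reports
their Pearson correlation and mean bias. On additive data the two should
agree closely; divergence flags either non-additive data or estimation
error concentrated in one model.

## The synthetic-data generator

Because destructive biomass datasets are rarely deposited, the package
ships a generator (`generate_trees`) that emulates the structure such a
study assumes, and every claim validated in this package is validated
against it:

* **Cohorts.** Default: 39 trees in three age cohorts (9 of age 7, 14 of
  age 16, 16 of age 28) with D ranges 5.7–16.3, 5.6–22.5, 8.7–28 cm and H
  ranges 4.9–9.3, 5.9–14.8, 10.3–22.7 m — the envelope of a typical
  multi-age plantation sample. Diameters are uniform within the cohort
  range.
* **Height given diameter.** Field studies report D and H marginals, not
  their joint law, so a modelling choice was needed: $\ln H$ follows the
  log-linear trend through the cohort's range endpoints plus $N(0,
  0.05^2)$ noise, clipped to the cohort H range. This is the simplest
  generator matching the marginal envelopes; it is a package choice, not an
  empirical claim about any real stand.
* **Biomass.** Each component is generated from its true allometry with
  lognormal multiplicative error, log-scale sd 0.2 by default — a realistic
  residual spread for component biomass — and the recorded total is exactly
  the component sum (additive truth). A consequence worth knowing: the sum
  of four power laws is not a power law, so even noiseless data leave the
  directly fitted *total* model a small (<1% of mean biomass) approximation
  error while the four component fits are exact.
* **Randomness.** One master seed; each component's noise comes from a
  sub-stream keyed by the component's fixed position, so adding a component
  leaves the others' values untouched.

`generate_literature` draws $(\alpha, b)$ pairs from a configured bivariate
normal. The default spread — sd 0.6 for $\alpha$, 0.06 for $b$, correlation
−0.9 — represents a realistic between-study dispersion, and the
configuration refuses positive correlations so synthetic compilations keep
the sign structure real ones show.

What the generator does **not** emulate: site and climate effects,
measurement error in D and H, non-additive component totals,
heteroscedasticity surviving the log transform, and non-lognormal error
tails. Tests passing on this generator therefore certify the estimation
machinery under the model's own assumptions, not robustness to their
violation.

## Validation design and problem sizes

The test suite validates the sampler against independent oracles rather
than against itself: with $\sigma^2$ held fixed the draws are compared to
the closed-form conjugate posterior (50 000 draws; means to 0.01,
covariances to 5%); under the flat prior the posterior must agree with
least squares to within 1% on a 39-tree sample; 95% credible intervals for
$b$ must cover the truth 88–99 times in 100 replicates at n = 50; and prior
elicitation must recover generating moments from 1 000 synthetic equations.

The small-sample value of the informative prior is tested as a win rate: at
n = 15, with a truth-centred prior, the informative fit must beat least
squares in well over half of 100 replicates. RMSE for that comparison is
measured on a common noiseless held-out stand (500 trees), because
in-sample kilogram-scale RMSE is close to the quantity least squares itself
optimises and would mostly measure overfit, not estimation error. The
wash-out of the prior at n = 2 000 is checked in-sample, where RMSE is
dominated by irreducible residual noise and the informative and
least-squares fits must agree to within 1%. These replicate counts and
sample sizes were chosen as the smallest that make the binomial and
Monte-Carlo error bands comfortably tighter than the margins being tested.

## Limitations

* Single-site, single-species scope: no hierarchical pooling across sites
  and no site-index covariates; the informative prior is the only channel
  for external information.
* The prior treats all literature equations as exchangeable and equally
  precise; equations from very different stand conditions get equal weight.
* $\sigma^2$ posteriors are exposed but have no external reference to be
  compared against.
* Evaluation offers no information criteria (AIC/DIC) or predictive
  scoring; MD/MAD/RMSE on the original scale are the only criteria, by
  design.
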