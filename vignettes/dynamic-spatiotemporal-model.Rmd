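---
title: "Dynamic spatio-temporal modelling of food-security panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic spatio-temporal modelling of food-security panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsndyn)
```

## The problem

Food security and nutrition (FSN) outcomes across a continent are shaped by
many interacting forces — nutrient intake, food supply, consumption status,
child care, environmental conditions, undernourishment, and so on — and the
strength of each force drifts over time. A static regression of a
country-year outcome (such as the number of severely food-insecure
individuals) on a fixed set of covariates misses exactly the feature analysts
care about: a covariate whose influence is negligible for a decade can become
decisive in a few years. fsndyn implements a two-stage workflow for annual
country-level panels:

1. **Factor reduction.** A wide table of correlated indicators (40 columns in
   the reference configuration) is compressed into a small number of
   orthogonal components by principal components analysis, with
   Kaiser–Meyer–Olkin and Bartlett sphericity diagnostics, the
   eigenvalue-greater-than-one retention rule, varimax rotation and
   regression-method scores.
2. **Dynamic hierarchical model.** The component scores enter a Bayesian
   spatio-temporal model whose regression coefficients follow a random walk
   over time and whose residual spatial structure is a Gaussian-process field
   whose variance and correlation range also evolve over time. The model is
   fitted by MCMC, validated by hold-out predictive-interval coverage, and
   summarised as coefficient/variance trajectories and percentile map layers.

## The model

Write \(Y_{st}\) for the (possibly transformed) response at site \(s\) and
year \(t = 1,\dots,T\), and \(x_{st}\) for the \(p\)-vector of covariates.
The hierarchy is

\[
\begin{aligned}
Y_{st} &= x_{st}^\top \beta_t + \aleph_{st} + \varepsilon_{st},
  &\varepsilon_{st} &\sim N(0, \sigma^2_{\varepsilon t}),\\
\beta_t &= \beta_{t-1} + \eta_t, &\eta_t &\sim N(0, \Sigma_\eta),\\
\aleph_{st} &= \aleph_{s,t-1} + \omega_{st},
  &\omega_{\cdot t} &\sim \mathrm{GP}\bigl(0,\,
    \sigma^2_{\omega t}\, e^{-\vartheta_t d}\bigr),
\end{aligned}
\]

with \(\beta_0 \sim N(d_0, \Sigma_0)\) and \(\aleph_{s,0} = 0\). The
observation-level variance \(\sigma^2_{\varepsilon t}\) (the *nugget*,
reported as `tau2`) captures unstructured micro-scale variation; the
innovation variance \(\sigma^2_{\omega t}\) of the spatial field (the
*partial sill*, reported as `sigma2`) measures how strongly spatially
structured shocks accumulate in year \(t\); and the decay \(\vartheta_t\)
(units 1/km, great-circle distance) sets the spatial correlation range, all
three per year. Priors: Gamma on both precisions, inverse-Wishart on
\(\Sigma_\eta\), and uniform on \(\vartheta_t\) over a bounded support.

The spatial innovation correlation is exponential,
\(\mathrm{corr}(d) = \exp(-\vartheta_t d)\) with \(d\) in kilometres. That is
the standard default for this model family; the family is isolated behind
`build_correlation()` so an alternative (e.g. Matérn) could be slotted in
without touching the sampler.

## Sampling scheme

`fit_dynamic_st()` runs a systematic-scan MCMC with six blocks per iteration,
in a fixed order chosen once for reproducibility
(β → ℵ → σ²ε → σ²ω → Σ\_η → ϑ):

* **Coefficient path** — exact joint draw of \(\beta_{0:T}\) by
  forward-filtering backward-sampling (FFBS): Kalman filter with identity
  evolution, evolution covariance \(\Sigma_\eta\), observation rows the
  covariates of the observed cells, then a backward pass. The \(t=0\) state
  is backward-sampled like any other, so the inverse-Wishart update of
  \(\Sigma_\eta\) below conditions on a *sampled* \(\beta_0\) and every block
  remains an exact full conditional of one joint model. (Fixing \(\beta_0\)
  at its prior mean instead would make the \(\Sigma_\eta\) conditional
  inconsistent with the FFBS marginal and fail a joint
  simulation-consistency check.)
* **Spatial field** — one exact joint draw of the whole \(n \times T\) field,
  again by FFBS with the field as the state vector (dimension \(n\)),
  evolution covariance \(\sigma^2_{\omega t} C_t\), and selection
  observations at the observed cells. Held-out cells are covered by the
  sampled field, which is what makes hold-out prediction a conditional
  (kriging-style) draw rather than a prior draw.
* **Nugget and sill paths** — conjugate Gamma updates per year.
* **Innovation covariance** — conjugate inverse-Wishart with the \(T\)
  recorded coefficient innovations.
* **Decay path** — per-year random-walk Metropolis on the log scale with the
  log-Jacobian in the acceptance ratio; proposals outside the uniform support
  are rejected outright. The step size adapts during burn-in only (so
  detailed balance holds afterwards), targeting the usual 20–45% acceptance
  band.

The chain starts from a neutral state: zero coefficient and spatial paths,
variances at their prior means, decay at the midpoint of its support.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_iter` / `burn_in` / `thin` | 5000 / 1000 / 1 | total iterations; burn-in and thinning are artifact choices recorded in every manifest |
| `d0`, `Sigma0` | 0, \(10^4 I\) | vague prior on the initial coefficients |
| `a_eps`, `b_eps` (= `a_w`, `b_w`) | 2, 1 | Gamma prior on each precision — proper, weakly informative, prior mean 2 |
| `wishart_df`, `wishart_scale` | \(p+2\), \(I\) | inverse-Wishart on \(\Sigma_\eta\); a diagonal-only switch is deliberately not provided (full by default) |
| `decay_bounds` | \((3/d_{\max},\, 3/d_{\min})\) | effective-range heuristic: correlation ≈ 0.05 at the largest / smallest intersite distance |
| `metropolis_step` | 0.3 | initial log-scale proposal sd, adapted in burn-in |
| `level` | 0.95 | credible / predictive interval level |

## The synthetic-data generator

Because the real indicator table is a bulk web resource, the package ships a
generator that emulates its statistical shape rather than its values:

* `simulate_indicators()` draws a block factor model
  \(x_j = \sqrt{\rho}\, f_{b(j)} + \sqrt{1-\rho}\,\nu\, e_j\) on a
  54 × 20 site-year grid (1080 rows) with 40 indicators in 10 blocks, then
  shifts/rescales columns to arbitrary measurement scales. With the default
  \(\rho = 0.7\) the sample correlation matrix has exactly 10 eigenvalues
  above 1 at this sample size, so the retention rule recovers the planted
  block count.
* `simulate_truth()` + `simulate_panel()` draw a response panel *exactly*
  from the hierarchy above with stored true parameters. The reference
  conditions are a unit-scale response with nugget variance 0.25, partial
  sill 0.16, coefficient-innovation sd 0.1 and decay 0.002/km (≈1500 km
  effective range) — values a continental annual panel plausibly exhibits
  once responses are standardised, chosen once and used unchanged by all
  recovery tests.
* Synthetic coordinates are uniform in Africa's bounding box
  (−20…55°E, −35…38°N); real centroids are a user-supplied CSV.

What passing tests on this test bed show — and do not show. The generator
produces Gaussian responses from the *correct* model, complete tables, and
exchangeable site-year noise. Recovery and coverage results on it therefore
validate the *implementation* (the samplers target the right posterior, the
intervals are calibrated when the model is true), not the model's adequacy
for real FAO-style data, which can be non-Gaussian, missing-not-at-random,
and subject to reporting biases the generator does not emulate.

## Numerical choices

* Distances are great-circle (haversine, WGS84 radius) in km via geosphere.
* Every factorization of a spatial correlation matrix adds a 1e−8 diagonal
  jitter (escalated only if factorization still fails); backward-sampling
  covariances are symmetrised and numerically zero covariances collapse the
  draw to its mean, so degenerate limits (\(\Sigma_\eta \to 0\),
  \(\sigma^2_\omega \to 0\)) behave exactly.
* Column standardisation in the factor stage uses the population (1/n)
  variance so scores are bit-reproducible; the correlation matrix is
  unaffected by that choice.
* Eigenvalue retention uses a strict "> 1": a tie at exactly 1 is excluded.
* Loading signs follow the convention that each component's
  largest-magnitude loading is positive, folded into the rotation matrix so
  `rotated = raw %*% rotation` holds exactly.
* Varimax runs pairwise planar rotations with the closed-form optimal angle;
  Kaiser row-normalization is on by default and exposed as a flag;
  non-convergence sets a flag instead of failing.
* Percentile map classes are rank-based
  (`ceiling(n_bins * rank / n)`, minimum-rank ties), which makes them
  invariant under strictly monotone transforms and sends tied sites to the
  lowest applicable class. The per-block aggregate is the median (outlier
  resistance); the mean is a flag away.
* All randomness flows from explicit `seed` arguments through scoped RNG
  (`withr::with_seed`); no function perturbs global RNG state unless asked.

## Design decisions on genuinely open points

* **Response scale.** The raw response for real data is a count; the model is
  Gaussian. Both an identity and a `log1p` transform are provided, the choice
  is recorded in every artifact header, and reporting back-transforms
  fitted values. The generator works on the model (Gaussian) scale.
* **Score method.** Regression scores; Bartlett or Anderson–Rubin scores
  were not implemented since nothing downstream depends on the score method
  beyond orthogonality in-sample.
* **Variance shares.** Component-specific variance percentages are reported
  both pre-rotation (eigenvalue shares) and post-rotation (sum-of-squares
  shares), labelled, since either convention is defensible.
* **Split unit.** The 70/30 hold-out defaults to random cells stratified by
  year (every year keeps training data); whole-site and whole-year splits
  are available and the manifest records which was used.
* **Held-out spatial effects** are conditional draws given the sampled
  field — the fitted spatial structure is used, as is standard for this
  model family — rather than marginal prior draws.
* **Chain count.** Single chain by default (per-seed multi-chain runs are a
  loop away); burn-in 1000 of 5000 and thinning 1 are artifact choices
  flagged in the run manifest.

## Problem sizes used in the test suite

Oracle checks run at deliberately tiny sizes where the exact posterior can be
formed directly: conjugate blocks at 20000–50000 draws, brute-force joint
Gaussian comparisons at \(n=4, T=3, p=1\) (12-dimensional stacked
posteriors), and a joint prior/Gibbs simulation-consistency check at
\(n=3, T=2, p=1\). Recovery and calibration checks run at the full study
geometry (54 × 20, three seeds; 5000-iteration chains for recovery,
2500 for coverage) — sizes chosen so the whole suite stays comfortably
reproducible on a single CPU.

## Worked example

```{r example, eval = FALSE}
library(fsndyn)

# synthetic study at reference conditions
ind <- simulate_indicators(indicator_spec(seed = 1))
fm <- fit_pca(ind)
glance(fm)

co <- simulate_coords(54, seed = 2)
tr <- simulate_truth(co, n_years = 20, p = 3, seed = 3)
pan <- simulate_panel(tr, seed = 4)

sp <- split_panel(pan, test_fraction = 0.3, seed = 5)
fit <- fit_dynamic_st(training_panel(pan, sp), n_iter = 5000,
                      burn_in = 1000, seed = 6)
assess_coverage(fit, sp, seed = 7)

autoplot(fit)                      # dynamic coefficients
plot_variance_trajectories(fit)    # sigma2 / tau2 paths
layers <- annual_fitted_layers(fit)
period_percentile_layers(layers)
```

Or end to end with artifact export:

```{r pipeline, eval = FALSE}
res <- run_pipeline(list(seed = 1), out_dir = "fsndyn-run")
```

## Known limitations

* Gaussian observation model only; counts enter through `log1p`.
* Exponential (isotropic) spatial correlation only, though pluggable.
* No proper scoring rules (CRPS, log score) — hold-out interval coverage is
  the single validation statistic, by design.
* No imputation: tables must be complete (impute upstream).
* The spatial FFBS is exact but \(O(n^3)\) per year; for hundreds of sites a
  low-rank approximation would be the natural extension (54 sites need
  none).
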