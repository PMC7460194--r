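---
title: "Spatiotemporally varying coefficient models for areal panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporally varying coefficient models for areal panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stvcareal)
```

## The problem

Areal space–time panels — one measurement per administrative unit per year,
such as hospital beds per 10,000 people per county over a decade — are
usually modelled with a single regression coefficient per covariate. That
stationarity assumption is exactly what an analyst of regional inequality
wants to interrogate: does personal income matter more in some counties than
others, and did its influence grow or fade over the decade? The
spatiotemporally varying coefficient (STVC) model answers both at once by
giving each covariate a spatially structured coefficient field (one value
per area, the *space-coefficients*, SC) plus a temporally structured
coefficient path (one value per year, the *time-coefficients*, TC).

## Model and priors

With `z = log y` and z-scored covariates `x`, the full model (model 5) is

$$z_{it} = \beta_0 + \sum_p (\mu_{p,i} + \gamma_{p,t})\,x_{itp} + \varepsilon_{it},
\qquad \varepsilon_{it} \sim N(0, \sigma^2).$$

Four simpler predictors are fit for comparison: global slopes only
(model 1), global slopes plus spatial and temporal random intercepts
(model 2), TC-only (model 3) and SC-only (model 4).

* **SC fields** follow the intrinsic CAR (Besag) prior on the contiguity
  graph: each area's coefficient is conditionally Normal around the mean of
  its neighbors with variance $\sigma_f^2 / m_i$. The structure matrix has
  $Q_{ii} = m_i$, $Q_{ij} = -1$ for neighbors, is rank-deficient by one per
  connected component, and its density is invariant to per-component
  constant shifts.
* **TC paths** follow a first-order random walk, the pairwise-difference
  penalty $\exp\{-\frac{1}{2\sigma_\gamma^2}\sum_t (\gamma_t -
  \gamma_{t-1})^2\}$, rank-deficient by one.
* **Hyperpriors**: each precision $1/\sigma_f^2$ (and the observation
  precision) gets a diffuse Gamma(shape 1, rate 5e-5) — vague enough that
  the data dominate, proper enough for conjugate updates. Both are
  configurable per structure.

Covariates that never change within an area (elevation, river density, ...)
get no TC path: a time path multiplying a time-constant covariate is not
distinguishable from the SC field.

### Identifiability and constraints

Adding a constant to every $\gamma_{p,t}$ and subtracting it from every
$\mu_{p,i}$ leaves the predictor unchanged, so exactly one member of each
SC/TC pair must be pinned. The scheme used here: **TC paths are constrained
to sum to zero and SC fields are left free**, so each SC field carries its
covariate's overall effect level (model 5 has no global slopes to carry
it). The space- and time-intercepts of model 2 are likewise sum-to-zero
with their level absorbed by $\beta_0$. In the TC-only model 3 no constraint
is applied: the path multiplies a non-constant covariate, so its level is
identified by the likelihood itself, and forcing a zero mean would forbid
model 3 from expressing any average covariate effect. Constraints are
re-imposed by centering after each Gibbs update with the removed mean added
to the absorbing block, an exact bookkeeping that leaves the predictor
untouched (verified to 1e-8 in the tests). For disconnected graphs the
centering is per component while only the global mean can be absorbed, so
exact predictor invariance is guaranteed on connected graphs — the shipped
study conditions; isolated areas are pinned to zero.

## Inference

After the log transform the likelihood is Gaussian, so every full
conditional is exact: each latent block (global terms, each SC field, each
TC path, the intercepts) is multivariate Normal with precision
$Q/\sigma_f^2 + D/\sigma^2$, where $D$ is diagonal because each observation
cell loads on exactly one coordinate of the block. The sampler is therefore
a blocked Gibbs scheme with Cholesky draws per block, conjugate Gamma
updates for all precisions, and data augmentation for missing response
cells (imputed from the current predictive each sweep — which is also what
produces complete estimated response maps at unobserved cells). A
deterministic-seed Laplace-style approximation is deliberately not used:
with exact conjugacy the MCMC targets the exact posterior, and chain
quality is monitored with split-R-hat (warning gate at 1.05) and
autocorrelation-based effective sample sizes on the global terms and
variance components.

Defaults are 2 chains of 5,000 iterations with half discarded; the shipped
tests and scripts use shorter, seed-fixed runs (200–1,500 kept draws per
chain on 100-area, 10-year panels), which the diagnostics show is ample for
these conjugate, low-autocorrelation updates at that size.

## What the synthetic generator emulates — and what it does not

`generate_panel()` produces the study conditions every downstream claim is
tested on: a rook-contiguity lattice (default 10×10, a miniature of a
real contiguity map with hundreds of counties), T = 10 years, five "SE" plus five "EX"
covariates of which two environmental ones are time-invariant, AR(1)
cross-correlation 0.4 between covariate columns (so the VIF screen has
collinearity to work on), true SC fields drawn from the constrained ICAR
itself (marginal sd 0.3), true TC paths from a centered RW1 (increment sd
0.1), observation noise sd 0.2 on the log scale, β₀ = log 30 putting the
median response near 30 per 10,000, and 5% of cells missing completely at
random. The defaults were fixed once as plausible field magnitudes —
no published variance components exist for this setting — and the truth
object records every latent quantity, so recovery is measurable exactly.

Because the true SC fields come from the same ICAR family the model
assumes, recovery tests are well-specified prior-matches-truth checks; the
`misspecified_sc` switch draws iid Gaussian fields instead to probe
robustness. The generator does **not** emulate real-yearbook features:
irregular county geometry, informative missingness (cells here are masked
completely at random), non-Gaussian response tails, measurement error in
covariates, or covariates without any true effect. Passing tests therefore
demonstrate internal correctness and well-specified recovery, not
performance on real administrative data.

One consequence visible in the analysis scripts: every generated covariate
carries true signal, so the screening stage (built for redundant candidate
pools) necessarily discards some signal, and the downstream R² on screened
panels is deflated relative to a fit on the full covariate set. That is a
property of the synthetic screening scenario, not of the model code.

## Screening

The two-step screen mirrors standard practice for large candidate pools:

1. **Iterative VIF filter, per block.** VIF$_j = 1/(1-R_j^2)$ from
   regressing column *j* on the rest; within the socioeconomic and
   environmental blocks separately, the worst offender above the threshold
   (default 5, the strict convention) is dropped and VIFs recomputed until
   all survive. Greedy drop-worst-and-recompute realizes "keep the most
   representative" and every round is logged so each elimination is
   auditable. Ties drop the later column; a block reduced to one covariate
   keeps it (VIF undefined at p = 1); perfect collinearity reports Inf.
2. **Random-forest importance.** A regression forest (500 trees,
   ⌈p/3⌉ features per split, fixed seed) ranks survivors by variance-
   reduction MDI (the regression analogue of Gini impurity, normalized to
   sum to one) and by unscaled permutation MDA on out-of-bag samples with
   10 repeats. The selection is the intersection of the two top-k sets
   (default k = ⌈p/2⌉, configurable since "half" of an odd survivor count
   is ambiguous), ordered by mean rank. Screening rows are pooled
   county-years.

## Model comparison

Six statistics per fit, all from the pointwise log-likelihood at observed
cells: DIC with the plug-in at the posterior-mean predictor and
posterior-mean observation variance (well-defined for every model 1–5),
WAIC with the summed posterior variance penalty via stable log-sum-exp,
the CPO-based leave-one-out log score LS = −mean log CPO (harmonic-mean
estimator with a per-cell effective-sample-size report rather than a
failure), and R² = 1 − SSE/SST computed on the log (model) scale with the
posterior-mean predictor, clamped to [0, 1]. Smaller is better for
everything but R². Under STVC truth the comparison reproduces the expected
qualitative pattern — the STVC model wins fit, prediction and explained
variation while paying the largest effective-parameter count.

## Spatial summaries

SC/TC posterior tables carry means and equal-tailed credible intervals on
the standardized covariate scale, flagged significant when the interval
excludes zero. Hot-spot maps use the Getis–Ord Gi\* statistic with
self-inclusive binary contiguity weights and the conventional 90/95/99%
thresholds — the clustering method is a presentation choice, exposed in
config, and no multiple-testing correction is applied by default to match
its descriptive use. Estimated response surfaces back-transform with the
full log-normal mean, `mean over draws of exp(η + σ²/2)`, which is unbiased
on the original scale, fills missing cells from the posterior predictive,
and smooths extreme single-cell outliers by construction.

## Numerical choices and limitations

* Standardization is pooled over all space–time cells (one mean/sd per
  covariate, population-sd convention) so coefficients share one scale;
  per-year z-scoring would confound the TC paths with rescaling.
* The natural log is used for the response; responses must be strictly
  positive, and zero cells are rejected at read time rather than fudged.
* Structure matrices are kept sparse; per-block Cholesky factors are taken
  dense because block dimensions here are at most a few hundred, where
  dense LAPACK factorization is faster than sparse bookkeeping.
* ICAR structure is used unscaled (σ² applies to the raw precision, the
  literal conditional form), not rescaled by generalized variance; the
  prior scales of SC and TC fields are therefore not directly comparable
  across graphs of different density.
* RW1 `scale` in the generator is the increment sd; ICAR `scale` is the
  average marginal sd. Degenerate scale 0 yields exact zero fields.
* Known limitations: no space–time interaction random effects, no proper
  CAR/Leroux or RW2 alternatives, no non-Gaussian likelihoods, and the
  harmonic-mean CPO estimator can be unstable for influential cells (the
  count of low-ESS cells is reported with each score).

## A small run

```{r example, eval = FALSE}
sim   <- generate_panel(sim_config(rows = 6, cols = 6, n_years = 8, seed = 1))
panel <- preprocess_panel(sim$panel)
scr   <- screen_covariates(panel, n_trees = 200, seed = 1)
panel <- subset_covariates(panel, scr$selected)
fits  <- lapply(1:5, function(m)
  fit_gibbs(build_model(stvc_model_spec(m, panel), panel, sim$graph),
            mcmc_config(chains = 2, iter = 1000, burnin = 500, seed = m)))
compare_models(lapply(fits, model_scorecard))
```
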