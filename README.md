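# stvcareal

Bayesian spatiotemporally varying coefficient (STVC) regression for areal
space–time panels, with the full analysis workflow around it: synthetic panel
generation with recorded ground truth, two-step covariate screening,
five nested hierarchical models fit by blocked Gibbs sampling, information-
criterion model comparison, and spatial/temporal coefficient products
(trend tables, coefficient maps, hot-spot classes, complete estimated
response surfaces).

The motivating setting is county-level healthcare-resource panels — hospital
beds per 10,000 people observed for each county and year — where the effect
of a socioeconomic or environmental covariate is not one number: it varies
smoothly over the map and over the decade. The package is for analysts who
want to fit and stress-test that class of model on areal panels where every
latent quantity is known, before trusting it on real data.

## The model

For area *i* = 1…I on an adjacency graph and year *t* = 1…T, the response is
modelled on the log scale,

    log y[i,t] = η[i,t] + ε[i,t],   ε[i,t] ~ N(0, σ²)

and the five nested predictors are

| model | predictor η[i,t] |
|---|---|
| 1 global | β₀ + Σₚ βₚ x[i,t,p] |
| 2 global + ST intercepts | model 1 + ξ[i] + ψ[t] |
| 3 TVC | β₀ + Σₚ γ[p,t] x[i,t,p] |
| 4 SVC | β₀ + Σₚ μ[p,i] x[i,t,p] |
| 5 STVC | β₀ + Σₚ (μ[p,i] + γ[p,t]) x[i,t,p] |

Each space-coefficient field μ[p,·] (and the space-intercept ξ) carries an
intrinsic CAR (Besag) prior on the areal graph: conditionally,
μ[p,i] ~ N(mean of neighbors, σ²ₚ/mᵢ) with mᵢ the neighbor count. Each
time-coefficient path γ[p,·] (and the time-intercept ψ) carries a first-order
random-walk prior penalizing squared successive differences. Time-invariant
covariates enter only the spatial terms. Variance components get diffuse
Gamma(1, 5e-5) priors on their precisions. Because the log-Gaussian
likelihood makes every full conditional an exact sparse Gaussian, inference
is by blocked Gibbs sampling with conjugate variance updates and
data-augmentation imputation of missing cells; sum-to-zero constraints keep
the paired fields identified. Models are compared on DIC, WAIC, their
effective-parameter counts, the CPO-based leave-one-out log score, and R².

## Worked example

```r
library(stvcareal)

sim   <- generate_panel(sim_config(rows = 10, cols = 10, n_years = 10,
                                   n_se = 3, n_ex = 0, n_time_invariant = 0,
                                   seed = 3))
panel <- preprocess_panel(sim$panel)           # log response, z-score covariates
fit   <- fit_gibbs(build_model(stvc_model_spec(5, panel), panel, sim$graph),
                   mcmc_config(chains = 2, iter = 800, burnin = 400, seed = 2))
fit
#> <stvc_fit> model 5: 800 draws (2 chains), max split-Rhat 1.007

cor(colMeans(fit$draws$sc_SE01), sim$truth$sc_fields[, 1])  # 0.959
cor(colMeans(fit$draws$tc_SE01), sim$truth$tc_paths[, 1])   # 0.977
unlist(model_scorecard(fit))[c("dic", "ls", "r2")]
#>        dic         ls         r2
#>  -9.178264   0.037586   0.914594
```

The fitted space-coefficient field for `SE01` correlates with the generating
field at r = 0.96 and the temporal path at r = 0.98; the STVC fit explains
91% of the log-response variation on this panel. `extract_sc_table()`,
`extract_tc_table()`, `getis_ord_gstar()` and `estimate_response_maps()`
turn a fit into per-area/per-year tables, hot-spot classes and complete
response surfaces (missing cells filled from the posterior predictive).

The numbered scripts under `analysis/` run the full study narrative —
simulate, screen (iterative VIF filter then random-forest MDI/MDA
selection), fit all five models, compare, and extract spatial summaries —
writing tables under `results/`. On the default synthetic conditions the
comparison reproduces the expected ordering: the STVC model attains the
lowest DIC/WAIC/LS and the highest R² of the five, at the price of the
largest effective parameter count.

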