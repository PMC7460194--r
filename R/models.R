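#' The five nested Bayesian regression models
#'
#' All five models share the log-Gaussian likelihood
#' `log y[i,t] ~ Normal(eta[i,t], sigma2)` and differ in the structure of the
#' additive predictor `eta`:
#'
#' 1. **Global regression** — intercept plus one global slope per covariate
#'    (flat priors): the stationary baseline.
#' 2. **Global + spatiotemporal intercepts** — model 1 plus an ICAR
#'    space-intercept (SI) and an RW1 time-intercept (TI), both sum-to-zero.
#' 3. **TVC** — intercept plus one RW1 time-coefficient (TC) path per
#'    time-varying covariate; no global slopes.
#' 4. **SVC** — intercept plus one ICAR space-coefficient (SC) field per
#'    covariate.
#' 5. **STVC** — intercept plus SC for every covariate and TC for every
#'    time-varying covariate; the full spatiotemporally varying model. TC
#'    paths are sum-to-zero with the removed mean absorbed into the paired SC
#'    field (the two share a flat direction); SC fields are unconstrained and
#'    carry each covariate's overall effect level.
#'
#' Time-invariant covariates never receive a TC path: a path multiplying a
#' covariate constant in time is not identified apart from the SC field.
#'
#' @param model_id integer 1-5.
#' @param panel a preprocessed [panel_data] (defines covariates and flags).
#' @return An object of class `stvc_spec`.
#' @export
stvc_model_spec <- function(model_id, panel) {
  stopifnot(inherits(panel, "panel_data"))
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:5) stopf("model_id must be in 1..5")
  covs <- panel$covariate_names
  tv <- covs[!panel$time_invariant]
  spec <- list(
    model_id = model_id,
    include_global_slopes = model_id %in% 1:2,
    include_si = model_id == 2L,
    include_ti = model_id == 2L,
    sc_covariates = if (model_id %in% 4:5) covs else character(0),
    tc_covariates = if (model_id %in% c(3L, 5L)) tv else character(0),
    likelihood = "log-gaussian"
  )
  structure(spec, class = "stvc_spec")
}

#' Assemble a model design from spec, panel and graph
#'
#' Emits the latent-block list the Gibbs sampler consumes: a flat-prior global
#' block (intercept, plus slopes for models 1-2), an ICAR `gmrf_spec` for each
#' SC/SI block, and an RW1 `gmrf_spec` for each TC/TI block. Constraint
#' bookkeeping: SI/TI are centered with the mean absorbed into the intercept;
#' TC is centered with the mean absorbed into the paired SC field (model 5
#' only — in model 3 the TC level multiplies a non-constant covariate and is
#' likelihood-identified, so no constraint is applied).
#'
#' @param spec an [stvc_model_spec()].
#' @param panel a preprocessed [panel_data] (log response, z-scored
#'   covariates).
#' @param graph an [area_graph] whose ids match the panel's areas.
#' @return An object of class `stvc_design`.
#' @export
build_model <- function(spec, panel, graph) {
  stopifnot(inherits(spec, "stvc_spec"), inherits(panel, "panel_data"),
            inherits(graph, "area_graph"))
  if (!panel$log_response || is.null(panel$standardization)) {
    stopf("panel must be preprocessed (preprocess_panel) before modelling")
  }
  if (!identical(graph$ids, panel$area_ids)) {
    stopf("graph areas do not match panel areas")
  }
  if (any(spec$tc_covariates %in% panel$covariate_names[panel$time_invariant])) {
    stopf("a time-invariant covariate cannot carry a time-coefficient path")
  }
  I <- length(panel$area_ids); T_ <- length(panel$years)
  P <- length(panel$covariate_names)
  blocks <- list()
  add <- function(b) blocks[[length(blocks) + 1L]] <<- b

  if (spec$include_global_slopes) {
    add(list(name = "global", kind = "global", dim = P + 1L, cov = NA_integer_,
             gmrf = NULL, constrained = FALSE, absorb = NULL))
  } else {
    add(list(name = "beta0", kind = "intercept", dim = 1L, cov = NA_integer_,
             gmrf = NULL, constrained = FALSE, absorb = NULL))
  }
  icar <- if (length(spec$sc_covariates) || spec$include_si) icar_structure(graph) else NULL
  rw1 <- if (length(spec$tc_covariates) || spec$include_ti) rw1_structure(T_) else NULL
  for (nm in spec$sc_covariates) {
    add(list(name = paste0("sc_", nm), kind = "sc", dim = I,
             cov = match(nm, panel$covariate_names), gmrf = icar,
             constrained = FALSE, absorb = NULL))
  }
  for (nm in spec$tc_covariates) {
    paired <- nm %in% spec$sc_covariates
    add(list(name = paste0("tc_", nm), kind = "tc", dim = T_,
             cov = match(nm, panel$covariate_names), gmrf = rw1,
             constrained = paired,
             absorb = if (paired) paste0("sc_", nm) else NULL))
  }
  if (spec$include_si) {
    add(list(name = "si", kind = "si", dim = I, cov = NA_integer_, gmrf = icar,
             constrained = TRUE, absorb = "intercept"))
  }
  if (spec$include_ti) {
    add(list(name = "ti", kind = "ti", dim = T_, cov = NA_integer_, gmrf = rw1,
             constrained = TRUE, absorb = "intercept"))
  }
  names(blocks) <- vapply(blocks, `[[`, "", "name")
  structure(
    list(spec = spec, panel = panel, graph = graph, blocks = blocks,
         noise_prior = c(shape = 1, rate = 5e-5)),
    class = "stvc_design"
  )
}

#' @export
print.stvc_design <- function(x, ...) {
  kinds <- vapply(x$blocks, `[[`, "", "kind")
  cat(sprintf("<stvc_design> model %d: %s\n", x$spec$model_id,
              paste(sprintf("%s(%d)", names(x$blocks),
                            vapply(x$blocks, `[[`, 0L, "dim")), collapse = " + ")))
  invisible(x)
}
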