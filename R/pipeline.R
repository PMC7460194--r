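#' Reproducible end-to-end pipeline
#'
#' `run_pipeline()` ties the stages together: simulate (or load) a panel,
#' screen covariates, fit the requested models, evaluate and compare them,
#' and extract spatial/temporal summaries from the best varying-coefficient
#' model. All randomness flows from one root seed through named per-stage
#' substreams, and the returned manifest makes every output traceable to
#' (config, seed).
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' A nested list fully serializable to/from YAML. Per-stage sections:
#' `generator` ([sim_config()] arguments), `screening`
#' ([screen_covariates()] arguments minus the panel), `mcmc`
#' ([mcmc_config()] arguments minus the seed), `models` (which of 1-5 to
#' fit), and `stages` (which stages to run).
#'
#' @param seed root integer seed.
#' @param generator,screening,mcmc stage settings (partial lists are merged
#'   over the defaults).
#' @param models integer vector of model ids to fit.
#' @param stages character subset of c("simulate", "screen", "fit",
#'   "evaluate", "summaries").
#' @export
run_config <- function(seed = 1, generator = list(), screening = list(),
                       mcmc = list(), models = 1:5,
                       stages = c("simulate", "screen", "fit", "evaluate", "summaries")) {
  merge_over <- function(defaults, user) {
    for (nm in names(user)) {
      if (!is.null(user[[nm]])) defaults[[nm]] <- user[[nm]]
    }
    defaults
  }
  list(
    seed = as.integer(seed),
    generator = merge_over(sim_config(), generator),
    screening = merge_over(
      list(vif_threshold = 5, k = NULL, n_trees = 500, n_perm = 10), screening),
    mcmc = merge_over(list(chains = 2, iter = 2000, burnin = 1000, thin = 1), mcmc),
    models = as.integer(models),
    stages = stages
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname load_run_config
#' @param config a [run_config()].
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @noRd
stage_seed <- function(root, stage) {
  offsets <- c(simulate = 11L, screen = 23L, fit = 37L, evaluate = 53L,
               summaries = 71L)
  root * 100L + offsets[[stage]]
}

#' Run the pipeline
#'
#' Executes the requested stages in order. Any stage error aborts with the
#' stage name; the partial manifest accumulated so far is attached to the
#' condition as its `partial_manifest` field.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, the panel CSV, GAL graph,
#'   truth summary, screening report, comparison table and summary tables are
#'   written there as plain-text files.
#' @return The run manifest: list(config, seed, selected covariates,
#'   comparison table, scorecards, diagnostics, summary tables, file paths).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  manifest <- list(config = config, seed = config$seed, outputs = list())
  in_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      cond <- simpleError(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
      cond$partial_manifest <- manifest
      stop(cond)
    })
  }
  emit <- function(name, obj, writer) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(out_dir, name)
      writer(obj, path)
      manifest$outputs[[name]] <<- path
    }
  }

  gen <- config$generator
  gen$seed <- stage_seed(config$seed, "simulate")
  sim <- in_stage("simulate", generate_panel(do.call(sim_config, gen)))
  panel <- in_stage("simulate", preprocess_panel(sim$panel))
  emit("panel.csv", sim$panel, write_panel_csv)
  emit("graph.gal", sim$graph, write_gal)
  emit("truth.json", sim$truth, function(tr, p) {
    jsonlite::write_json(list(beta0 = tr$beta0, sigma_obs = tr$sigma_obs,
                              field_scales = as.list(tr$field_scales),
                              seed = tr$seed), p, auto_unbox = TRUE)
  })

  model_panel <- panel
  if ("screen" %in% config$stages) {
    sc <- config$screening
    screening <- in_stage("screen", screen_covariates(
      panel, vif_threshold = sc$vif_threshold, k = sc$k,
      n_trees = sc$n_trees, n_perm = sc$n_perm,
      seed = stage_seed(config$seed, "screen")))
    manifest$screening <- list(
      retained_after_vif = screening$retained_after_vif,
      selected = screening$selected)
    emit("screening_vif.csv", screening$vif_table,
         function(o, p) utils::write.csv(o, p, row.names = FALSE))
    if (length(screening$selected) >= 1) {
      model_panel <- in_stage("screen", subset_covariates(panel, screening$selected))
    }
  }

  fits <- list()
  if ("fit" %in% config$stages) {
    mc <- config$mcmc
    for (mid in config$models) {
      cfg <- mcmc_config(chains = mc$chains, iter = mc$iter, burnin = mc$burnin,
                         thin = mc$thin,
                         seed = stage_seed(config$seed, "fit") + mid)
      fits[[as.character(mid)]] <- in_stage("fit", fit_gibbs(
        build_model(stvc_model_spec(mid, model_panel), model_panel, sim$graph), cfg))
    }
    manifest$diagnostics <- lapply(fits, function(f) f$diagnostics)
    manifest$rhat_warnings <- vapply(fits, function(f) isTRUE(f$rhat_warning), TRUE)
  }

  if ("evaluate" %in% config$stages && length(fits) >= 1) {
    cards <- in_stage("evaluate", lapply(fits, model_scorecard))
    manifest$scorecards <- cards
    if (length(cards) >= 2) {
      manifest$comparison <- in_stage("evaluate", compare_models(unname(cards)))
      emit("comparison.csv", manifest$comparison,
           function(o, p) utils::write.csv(o, p, row.names = FALSE))
    }
  }

  if ("summaries" %in% config$stages && length(fits) >= 1) {
    pick <- intersect(c("5", "4", "3"), names(fits))
    best <- fits[[if (length(pick)) pick[1] else names(fits)[1]]]
    manifest$summary_model <- best$design$spec$model_id
    if (any(vapply(best$design$blocks, function(b) b$kind == "sc", TRUE))) {
      sc_tab <- in_stage("summaries", extract_sc_table(best))
      manifest$sc_table <- sc_tab
      emit("sc_table.csv", sc_tab, function(o, p) utils::write.csv(o, p, row.names = FALSE))
      first_cov <- sc_tab$covariate[1]
      manifest$hotspots <- in_stage("summaries", getis_ord_gstar(
        sc_tab$mean[sc_tab$covariate == first_cov], sim$graph))
      emit("hotspots.csv", manifest$hotspots,
           function(o, p) utils::write.csv(o, p, row.names = FALSE))
    }
    if (any(vapply(best$design$blocks, function(b) b$kind == "tc", TRUE))) {
      tc_tab <- in_stage("summaries", extract_tc_table(best))
      manifest$tc_table <- tc_tab
      emit("tc_table.csv", tc_tab, function(o, p) utils::write.csv(o, p, row.names = FALSE))
    }
    maps <- in_stage("summaries", estimate_response_maps(best))
    manifest$response_maps <- maps
    emit("response_mean.csv", maps$mean,
         function(o, p) utils::write.csv(as.data.frame(o), p))
  }

  manifest$truth <- sim$truth
  manifest
}
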