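#!/usr/bin/env Rscript
# Stage 3: fit the five nested Bayesian models on the screened covariate set
# by blocked Gibbs sampling, then score each with DIC/WAIC/P_DIC/P_WAIC/LS/R2
# and write the comparison table. Reads results/data/ and results/screening/,
# writes results/models/.

suppressPackageStartupMessages(library(stvcareal))
cfg <- load_run_config("analysis/config.yaml")
dir.create("results/models", showWarnings = FALSE, recursive = TRUE)

panel <- preprocess_panel(read_panel_csv("results/data/panel.csv"))
graph <- read_gal("results/data/graph.gal")
sel <- jsonlite::read_json("results/screening/selection.json",
                           simplifyVector = TRUE)$selected
if (length(sel) >= 1) panel <- subset_covariates(panel, sel)
cat("modelling covariates:", paste(panel$covariate_names, collapse = ", "), "\n")

cards <- list()
for (mid in cfg$models) {
  t0 <- Sys.time()
  fit <- fit_gibbs(
    build_model(stvc_model_spec(mid, panel), panel, graph),
    mcmc_config(chains = cfg$mcmc$chains, iter = cfg$mcmc$iter,
                burnin = cfg$mcmc$burnin, seed = cfg$seed + mid)
  )
  cards[[as.character(mid)]] <- model_scorecard(fit)
  utils::write.csv(fit$diagnostics,
                   sprintf("results/models/diagnostics_model%d.csv", mid),
                   row.names = FALSE)
  utils::write.csv(posterior_summary(fit),
                   sprintf("results/models/posterior_model%d.csv", mid),
                   row.names = FALSE)
  cat(sprintf("model %d: %.1fs, max Rhat %.3f%s\n", mid,
              as.numeric(Sys.time() - t0, units = "secs"),
              max(fit$diagnostics$rhat, na.rm = TRUE),
              if (isTRUE(fit$rhat_warning)) " [warning]" else ""))
}

tab <- compare_models(unname(cards))
utils::write.csv(tab, "results/models/comparison.csv", row.names = FALSE)
print(tab[, c("model", "dic", "waic", "p_dic", "p_waic", "ls", "r2")])
winner <- tab$model[tab$best_dic]
cat(sprintf("best model by DIC: %d (STVC expected under spatiotemporal truth)\n",
            winner))
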