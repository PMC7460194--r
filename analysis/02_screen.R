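#!/usr/bin/env Rscript
# Stage 2: two-step covariate screening — iterative VIF filter per block,
# then random-forest MDI/MDA ranking with top-k intersection selection.
# Reads results/data/, writes results/screening/.

suppressPackageStartupMessages(library(stvcareal))
cfg <- load_run_config("analysis/config.yaml")
dir.create("results/screening", showWarnings = FALSE, recursive = TRUE)

panel <- preprocess_panel(read_panel_csv("results/data/panel.csv"))
res <- screen_covariates(panel,
                         vif_threshold = cfg$screening$vif_threshold,
                         n_trees = cfg$screening$n_trees,
                         seed = cfg$seed + 1)

utils::write.csv(res$vif_table, "results/screening/vif_rounds.csv", row.names = FALSE)
utils::write.csv(
  data.frame(covariate = names(res$mdi), mdi = res$mdi,
             mda = res$mda[names(res$mdi)],
             selected = names(res$mdi) %in% res$selected),
  "results/screening/importance.csv", row.names = FALSE)
jsonlite::write_json(
  list(retained_after_vif = res$retained_after_vif, selected = res$selected,
       config = res$config),
  "results/screening/selection.json", auto_unbox = TRUE)

print(res)
cat("VIF eliminations:",
    paste(res$vif_table$covariate[res$vif_table$dropped], collapse = ", "), "\n")
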