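#!/usr/bin/env Rscript
# Stage 1: simulate the county x year panel with recorded ground truth.
# Writes the panel (long CSV), the contiguity graph (GAL) and a truth summary
# under results/data/.

suppressPackageStartupMessages(library(stvcareal))
cfg <- load_run_config("analysis/config.yaml")
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

gen <- cfg$generator
gen$seed <- cfg$seed
sim <- generate_panel(do.call(sim_config, gen))

write_panel_csv(sim$panel, "results/data/panel.csv")
write_gal(sim$graph, "results/data/graph.gal")
jsonlite::write_json(
  list(beta0 = sim$truth$beta0, sigma_obs = sim$truth$sigma_obs,
       field_scales = as.list(sim$truth$field_scales), seed = sim$truth$seed),
  "results/data/truth.json", auto_unbox = TRUE)
utils::write.csv(data.frame(area_id = rownames(sim$truth$sc_fields),
                            sim$truth$sc_fields),
                 "results/data/truth_sc_fields.csv", row.names = FALSE)

print(sim$panel)
print(sim$graph)
cat(sprintf("response range (observed): %.1f - %.1f per 10,000\n",
            min(sim$panel$y, na.rm = TRUE), max(sim$panel$y, na.rm = TRUE)))
cat(sprintf("missing cells: %d of %d\n", sum(is.na(sim$panel$y)),
            length(sim$panel$y)))
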