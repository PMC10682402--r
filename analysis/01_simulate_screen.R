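#!/usr/bin/env Rscript
# Step 1 — simulate the deletion screen.
#
# Generates the synthetic 25-strain screen described in
# inst/extdata/screen_config.yaml: per-cell division counts with
# dead/alive end states from 72-h experiments, 200 cells per strain
# pooled from two replicates. Writes the cell-level table and the
# ground-truth parameters so later steps can be checked against what the
# generator actually used.

library(rlsfit)

config_path <- system.file("extdata", "screen_config.yaml", package = "rlsfit")
cfg <- read_sim_config(config_path)
message("design: ", cfg$design$n_cells, " cells/strain, ",
        cfg$design$duration_h, " h, seed ", cfg$design$seed)

sim <- simulate_screen(cfg$strain_specs, cfg$design, cfg$wildtype_id)

dir.create("results", showWarnings = FALSE)
write_cell_table(sim$cells, "results/cells.tsv")
utils::write.table(sim$truth, "results/truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cen <- tapply(sim$cells$end_state == "censored", sim$cells$strain, mean)
message(nrow(sim$truth), " strains, ", nrow(sim$cells), " cells; ",
        "censored fraction ", sprintf("%.1f", 100 * min(cen)), "-",
        sprintf("%.1f", 100 * max(cen)), "% per strain")
message("wrote results/cells.tsv and results/truth.tsv")
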