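#!/usr/bin/env Rscript
# Stage 6 — reporting tables.
#
# A one-row-per-trait table of meta-analyzed ORs and HRs per endpoint
# (basic model), and the paired OR-vs-HR export with significance
# categories for the usual prevalent-vs-incident scatter.

source("analysis/00_config.R")

meta <- readRDS(stage_path("meta.rds"))
panel <- read_glycan_panel(tpng_panel_file())
defs <- read_trait_panel(panel = panel)

report <- report_table(meta, defs, model = "model1")
save_table(report, "trait_report_model1.tsv")

pairs <- effect_pairs(meta, model = "model1")
save_table(pairs, "effect_pairs_model1.tsv")
message("significance categories (prevalent OR vs incident HR):")
print(table(pairs$category))
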