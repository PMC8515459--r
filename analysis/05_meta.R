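#!/usr/bin/env Rscript
# Stage 5 — random-effects meta-analysis across the two cohorts and FDR.
#
# DerSimonian-Laird pooling per trait within every endpoint x design x
# model stratum, I-squared heterogeneity, and Benjamini-Hochberg FDR over
# the 45 traits of each stratum.

source("analysis/00_config.R")

assoc_all <- readRDS(stage_path("associations.rds"))
meta <- meta_analyze(assoc_all)
saveRDS(meta, stage_path("meta.rds"))

sig <- meta[!is.na(meta$p_fdr) & meta$p_fdr < 0.05, ]
message(nrow(sig), " trait-endpoint-design-model results FDR-significant")
top <- sig[order(sig$p), c("trait", "endpoint", "design", "model",
                           "effect", "i2", "p", "p_fdr")]
print(utils::head(top, 10), row.names = FALSE)
save_table(top, "fdr_significant.tsv")

truth <- readRDS(stage_path("sim_diagene.rds"))$truth
recov <- merge(truth, meta[meta$model == "model1", ],
               by = c("trait", "endpoint", "design"))
recov <- recov[, c("trait", "endpoint", "design", "beta.x", "beta.y",
                   "se", "p_fdr")]
names(recov)[4:5] <- c("planted_beta", "estimated_beta")
message("planted vs estimated (model 1):")
print(recov, row.names = FALSE)
save_table(recov, "planted_vs_estimated.tsv")
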