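# Shared configuration for the numbered analysis scripts. Each script is a
# thin narrative driver over the tpng package; intermediates live under
# scratch/analysis/ and small summary tables under results/analysis/.

library(tpng)

cfg <- default_sim_config()
seed <- 1L
m_imputations <- 5L  # completed tables pooled by Rubin's rules

scratch_dir <- "scratch/analysis"
results_dir <- "results/analysis"
dir.create(scratch_dir, showWarnings = FALSE, recursive = TRUE)
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)

hash <- config_hash(cfg)
stage_path <- function(name) file.path(scratch_dir, name)
result_path <- function(name) file.path(results_dir, name)

save_table <- function(tab, name) {
  con <- file(result_path(name), "w")
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  write.table(format(tab, digits = 6), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)
  message("wrote ", result_path(name))
}
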