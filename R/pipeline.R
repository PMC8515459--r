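#' Hash of a configuration
#'
#' 31-bit polynomial rolling hash over the deparsed configuration, as a
#' hex string; stamped into every output file header so a run's outputs
#' are traceable to one configuration and seed.
#'
#' @param config any R object.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_stage_tsv <- function(tab, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Preprocess one cohort's raw spectra into analysis-ready traits
#'
#' Applies the preprocessing chain in the fixed order: quality control on
#' raw spectra, total-area normalization, derived-trait computation,
#' replicate precision (derived traits and direct compositions), batch
#' correction (on derived traits by default; a switch corrects the
#' composition abundances instead) and Z-scaling of the clinical samples.
#'
#' @param raw wells x compositions intensity matrix.
#' @param info well metadata (sample_id, plate, is_replicate,
#'   replicate_group).
#' @param defs,panel trait definitions and annotated panel.
#' @param batch_on `"traits"` (default) or `"compositions"`.
#' @return list: `traits` (Z-scaled, clinical), `traits_raw`, `abundance`,
#'   `info`, `rsd`, `rsd_direct`, `exclusions`.
#' @export
preprocess_cohort <- function(raw, info, defs, panel,
                              batch_on = c("traits", "compositions")) {
  batch_on <- match.arg(batch_on)
  qc <- qc_filter(raw)
  info <- info[match(rownames(qc$raw), info$sample_id), ]
  ab <- total_area_normalize(qc$raw)
  if (batch_on == "compositions") {
    clin <- !info$is_replicate
    ab[clin, ] <- batch_correct(ab[clin, , drop = FALSE], info$plate[clin])
    ab[ab < 0] <- 0
    ab <- ab / rowSums(ab)
  }
  traits <- compute_traits(ab, defs, panel)
  rsd <- replicate_rsd(traits, info$replicate_group)
  rsd_direct <- replicate_rsd(ab, info$replicate_group)
  clin <- !info$is_replicate
  traits_clin <- traits[clin, , drop = FALSE]
  if (batch_on == "traits") {
    traits_clin <- batch_correct(traits_clin, info$plate[clin])
  }
  list(traits = zscale(traits_clin), traits_raw = traits_clin,
       abundance = ab, info = info, rsd = rsd, rsd_direct = rsd_direct,
       exclusions = rbind(qc$exclusions, attr(ab, "exclusions")))
}

#' Run the per-trait association screen for one cohort
#'
#' Derives non-HDL cholesterol, imputes the covariates (single completed
#' table or m > 1 with Rubin pooling), splits every endpoint into its
#' prevalent and incident analysis sets, and fits the per-trait logistic
#' and Cox models under the requested adjustment models.
#'
#' @param traits_z Z-scaled trait matrix (clinical samples, row names =
#'   subject ids).
#' @param covariates covariate data.frame (may contain missing values).
#' @param records endpoint long table (see [split_prevalent_incident()]).
#' @param cohort_name label written into the result rows.
#' @param models adjustment models to fit.
#' @param m imputation count.
#' @param seed seed for the imputation chains.
#' @return data.frame of per-trait results across endpoints, designs and
#'   models.
#' @export
associate_cohort <- function(traits_z, covariates, records, cohort_name,
                             models = c("model1", "full"), m = 1L,
                             seed = 1L) {
  sets <- split_prevalent_incident(records)
  covariates <- derive_non_hdl(covariates)
  impute_vars <- intersect(c("bmi", "hdl", "non_hdl", "sbp", "hba1c",
                             "smoking", "diabetes_duration", "creatinine"),
                           names(covariates))
  completed <- mice_impute(covariates, vars = impute_vars, m = m, seed = seed)
  ids <- rownames(traits_z)
  res <- list()
  for (ep in names(sets)) {
    for (model in models) {
      prev <- sets[[ep]]$prevalent
      keep <- match(prev$subject_id, ids)
      ok <- !is.na(keep)
      fits <- lapply(completed, function(cv) {
        cv <- cv[match(prev$subject_id[ok], cv$subject_id), ]
        fit_logistic(traits_z[keep[ok], , drop = FALSE], cv,
                     prev$case[ok], model, ep)
      })
      tab <- pool_rubin(fits)
      tab$endpoint <- ep; tab$design <- "prevalent-logistic"
      tab$model <- model; tab$cohort <- cohort_name
      res[[length(res) + 1L]] <- tab

      inc <- sets[[ep]]$incident
      keep <- match(inc$subject_id, ids)
      ok <- !is.na(keep)
      fits <- lapply(completed, function(cv) {
        cv <- cv[match(inc$subject_id[ok], cv$subject_id), ]
        fit_cox(traits_z[keep[ok], , drop = FALSE], cv,
                inc$event[ok], inc$time[ok], model, ep)
      })
      tab <- pool_rubin(fits)
      tab$endpoint <- ep; tab$design <- "incident-cox"
      tab$model <- model; tab$cohort <- cohort_name
      res[[length(res) + 1L]] <- tab
    }
  }
  do.call(rbind, res)
}

#' Table-shaped summary of the meta-analyzed screen
#'
#' One row per trait with the meta-analyzed prevalent OR and incident HR
#' and their (FDR-adjusted) p values per endpoint, for one adjustment
#' model.
#'
#' @param meta output of [meta_analyze()].
#' @param defs trait definitions (for descriptions).
#' @param model adjustment model (default `"model1"`).
#' @return wide data.frame.
#' @export
report_table <- function(meta, defs, model = "model1") {
  out <- data.frame(trait = defs$name, description = defs$description,
                    stringsAsFactors = FALSE)
  for (ep in unique(meta$endpoint)) {
    prev <- meta[meta$endpoint == ep & meta$model == model &
                   meta$design == "prevalent-logistic", ]
    inc <- meta[meta$endpoint == ep & meta$model == model &
                  meta$design == "incident-cox", ]
    i1 <- match(out$trait, prev$trait)
    i2 <- match(out$trait, inc$trait)
    out[[paste0(ep, "_or")]] <- prev$effect[i1]
    out[[paste0(ep, "_or_p")]] <- prev$p[i1]
    out[[paste0(ep, "_or_p_fdr")]] <- prev$p_fdr[i1]
    out[[paste0(ep, "_hr")]] <- inc$effect[i2]
    out[[paste0(ep, "_hr_p")]] <- inc$p[i2]
    out[[paste0(ep, "_hr_p_fdr")]] <- inc$p_fdr[i2]
  }
  out
}

#' Run the full two-cohort analysis pipeline on synthetic data
#'
#' Simulates both cohorts, then runs every analysis stage: quality
#' control, total-area normalization, derived-trait computation, replicate
#' precision, empirical-Bayes batch correction, Z-scaling, covariate
#' imputation, endpoint splitting (prevalent nephropathy re-derived from
#' the ACR trajectories through the case rule), per-trait logistic and Cox
#' models under both adjustment models, DerSimonian-Laird meta-analysis
#' with I-squared, and Benjamini-Hochberg FDR per endpoint x design x
#' model family. Optionally writes each stage's tables as TSV with a
#' config-hash header.
#'
#' @param config simulation configuration.
#' @param seed integer master seed; every stage seed derives from it.
#' @param out_dir optional output directory.
#' @param models adjustment models to fit.
#' @param m imputation count used for analysis (1 = single completed
#'   dataset; >1 pools by Rubin's rules).
#' @return list: per-cohort stage outputs, combined association table,
#'   meta-analysis, report and effect-pair tables, truth, manifest.
#' @export
run_pipeline <- function(config = default_sim_config(), seed = 1L,
                         out_dir = NULL, models = c("model1", "full"),
                         m = 1L) {
  panel <- read_glycan_panel(tpng_panel_file())
  defs <- read_trait_panel(panel = panel)
  hash <- config_hash(config)
  cohorts <- names(config$cohorts)
  assoc <- list()
  stage <- list()
  for (i in seq_along(cohorts)) {
    cname <- cohorts[i]
    sim <- simulate_cohort(cname, config, seed = seed + 1000L * i,
                           panel = panel, defs = defs)
    pre <- preprocess_cohort(sim$raw, sim$info, defs, panel)
    records <- sim$records
    neph <- nephropathy_cases(sim$acr)
    idx <- records$endpoint == "nephropathy"
    records$prevalent[idx] <-
      neph$case[match(records$subject_id[idx], neph$subject_id)]
    assoc[[cname]] <- associate_cohort(pre$traits, sim$covariates, records,
                                       cname, models = models, m = m,
                                       seed = seed + 1000L * i + 500L)
    stage[[cname]] <- list(sim = sim, pre = pre, records = records)
  }
  assoc_all <- do.call(rbind, assoc)
  meta <- meta_analyze(assoc_all)
  report <- report_table(meta, defs)
  pairs <- effect_pairs(meta)
  truth <- stage[[1]]$sim$truth
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stage_tsv(assoc_all, file.path(out_dir, "associations.tsv"),
                    hash, seed)
    write_stage_tsv(meta, file.path(out_dir, "meta_analysis.tsv"),
                    hash, seed)
    write_stage_tsv(report, file.path(out_dir, "trait_report.tsv"),
                    hash, seed)
    write_stage_tsv(pairs, file.path(out_dir, "effect_pairs.tsv"),
                    hash, seed)
    write_stage_tsv(truth, file.path(out_dir, "planted_truth.tsv"),
                    hash, seed)
    for (cname in cohorts) {
      rsd <- stage[[cname]]$pre$rsd
      write_stage_tsv(
        data.frame(trait = names(rsd$per_trait),
                   rsd_pct = unname(rsd$per_trait)),
        file.path(out_dir, paste0("replicate_rsd_", cname, ".tsv")),
        hash, seed)
      write_stage_tsv(stage[[cname]]$pre$exclusions,
                      file.path(out_dir, paste0("qc_exclusions_", cname,
                                                ".tsv")), hash, seed)
    }
  }
  list(stage = stage, assoc = assoc_all, meta = meta, report = report,
       pairs = pairs, truth = truth,
       manifest = list(config_hash = hash, seed = seed, models = models,
                       m = m, cohorts = cohorts))
}
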