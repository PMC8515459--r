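#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools k study estimates with inverse-variance fixed-effect weights
#' `w = 1/se^2`, Cochran's `Q = sum w (b - b_FE)^2`, the method-of-moments
#' between-study variance `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 /
#' sum w))`, re-weighting `w* = 1/(se^2 + tau2)`, and a normal-reference
#' two-sided p value. With `tau2 = 0` this reduces exactly to
#' fixed-effect inverse-variance pooling.
#'
#' @param betas,ses numeric vectors of per-study log effects and standard
#'   errors (k >= 2, all SE > 0).
#' @return list: `beta`, `se`, `q`, `tau2`, `i2` (percent), `z`, `p`, `k`.
#' @export
dersimonian_laird <- function(betas, ses) {
  k <- length(betas)
  if (k < 2L) stop("meta-analysis needs at least 2 studies, got ", k)
  if (length(ses) != k) stop("betas and ses differ in length")
  if (any(!is.finite(ses)) || any(ses <= 0)) stop("all SEs must be positive")
  w <- 1 / ses^2
  b_fe <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - b_fe)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (ses^2 + tau2)
  beta <- sum(ws * betas) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  z <- beta / se
  list(beta = beta, se = se, q = q, tau2 = tau2, i2 = i_squared(q, k),
       z = z, p = 2 * stats::pnorm(-abs(z)), k = k)
}

#' I-squared heterogeneity
#'
#' Percentage of between-study variability attributable to heterogeneity
#' rather than chance: `max(0, (Q - (k - 1)) / Q) * 100`, with Q = 0
#' mapping to 0.
#'
#' @param q Cochran's Q (>= 0).
#' @param k number of studies (>= 2).
#' @return percentage in [0, 100].
#' @export
i_squared <- function(q, k) {
  stopifnot(q >= 0, k >= 2)
  if (q == 0) return(0)
  max(0, (q - (k - 1)) / q) * 100
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values (monotone, order-preserving) via
#' `stats::p.adjust(method = "BH")`, applied per family of meta-analyzed
#' traits (one family per endpoint x design x model).
#'
#' @param pvals p values in (0, 1].
#' @return adjusted p values.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] <= 0 | pvals[ok] > 1)) {
    stop("p values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Meta-analyze per-cohort association results
#'
#' Runs [dersimonian_laird()] per trait across cohorts within every
#' endpoint x design x model stratum of a combined association table, then
#' applies [bh_fdr()] within each stratum (the FDR family is the full set
#' of meta-analyzed traits, significant or not). Traits flagged in any
#' cohort (separation / monotone likelihood) are excluded with a missing
#' pooled result.
#'
#' @param assoc data.frame with columns `trait, endpoint, design, model,
#'   cohort, beta, se` (and optionally `flagged`).
#' @return data.frame: trait, endpoint, design, model, beta, se, effect,
#'   q, tau2, i2, p, p_fdr.
#' @export
meta_analyze <- function(assoc) {
  need <- c("trait", "endpoint", "design", "model", "cohort", "beta", "se")
  stopifnot(all(need %in% names(assoc)))
  if (!"flagged" %in% names(assoc)) assoc$flagged <- FALSE
  strata <- unique(assoc[, c("endpoint", "design", "model")])
  out <- list()
  for (s in seq_len(nrow(strata))) {
    sub <- merge(assoc, strata[s, , drop = FALSE])
    rows <- lapply(unique(sub$trait), function(tr) {
      st <- sub[sub$trait == tr, ]
      base <- data.frame(trait = tr, endpoint = st$endpoint[1],
                         design = st$design[1], model = st$model[1],
                         stringsAsFactors = FALSE)
      if (any(st$flagged) || anyNA(st$beta) || anyNA(st$se)) {
        return(cbind(base, beta = NA_real_, se = NA_real_, effect = NA_real_,
                     q = NA_real_, tau2 = NA_real_, i2 = NA_real_,
                     p = NA_real_))
      }
      dl <- dersimonian_laird(st$beta, st$se)
      cbind(base, beta = dl$beta, se = dl$se, effect = exp(dl$beta),
            q = dl$q, tau2 = dl$tau2, i2 = dl$i2, p = dl$p)
    })
    tab <- do.call(rbind, rows)
    tab$p_fdr <- NA_real_
    ok <- !is.na(tab$p)
    tab$p_fdr[ok] <- bh_fdr(tab$p[ok])
    out[[s]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired odds-ratio vs hazard-ratio export
#'
#' Pairs each trait's prevalent (logistic, OR) and incident (Cox, HR)
#' meta-analyzed effects per endpoint for a given model, with a
#' significance category mirroring the usual OR-vs-HR scatter legend.
#'
#' @param meta output of [meta_analyze()].
#' @param model which adjustment model to pair (default `"model1"`).
#' @param alpha significance level (default 0.05).
#' @return data.frame: trait, endpoint, or_prevalent, hr_incident, and the
#'   per-arm p values plus a `category` string.
#' @export
effect_pairs <- function(meta, model = "model1", alpha = 0.05) {
  prev <- meta[meta$design == "prevalent-logistic" & meta$model == model, ]
  inc <- meta[meta$design == "incident-cox" & meta$model == model, ]
  tab <- merge(prev[, c("trait", "endpoint", "effect", "p", "p_fdr")],
               inc[, c("trait", "endpoint", "effect", "p", "p_fdr")],
               by = c("trait", "endpoint"), suffixes = c("_prev", "_inc"))
  names(tab)[names(tab) == "effect_prev"] <- "or_prevalent"
  names(tab)[names(tab) == "effect_inc"] <- "hr_incident"
  cat_of <- function(pp, pfp, pi, pfi) {
    if (is.na(pp) || is.na(pi)) return("unavailable")
    if (pfp < alpha && pfi < alpha) return("prevalent+incident FDR")
    if (pfp < alpha && pi < alpha) return("prevalent FDR, incident nominal")
    if (pfp < alpha) return("prevalent FDR")
    if (pfi < alpha) return("incident FDR")
    if (pi < alpha) return("incident nominal")
    if (pp < alpha) return("prevalent nominal")
    "not significant"
  }
  tab$category <- mapply(cat_of, tab$p_prev, tab$p_fdr_prev, tab$p_inc,
                         tab$p_fdr_inc)
  tab
}

#' Arithmetic cross-checks on the published cohort summary
#'
#' Recomputes, from the packaged published summary of the two cohorts,
#' the pooled prevalent case counts per complication, the percentages
#' implied by the printed case/total counts (incident percentages against
#' the shown risk-set totals; prevalent percentages under both conventions
#' found in the published table, against the full cohort n and against the
#' shown totals), and the non-HDL cholesterol mean as total cholesterol
#' minus HDL-c via [derive_non_hdl()].
#'
#' @param path summary TSV (defaults to the packaged file).
#' @return named list of computed quantities.
#' @export
cohort_summary_checks <- function(path = system.file(
  "extdata", "cohort_summary_published.tsv", package = "tpng",
  mustWork = TRUE)) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  val <- function(cohort, item) {
    tab$value[tab$cohort == cohort & tab$item == item]
  }
  out <- list()
  for (ep in c("cvd", "nephropathy", "retinopathy")) {
    out[[paste0("pooled_prevalent_", ep, "_cases")]] <-
      val("diagene", paste0("prevalent_", ep, "_cases")) +
      val("dcs", paste0("prevalent_", ep, "_cases"))
    out[[paste0("pooled_incident_", ep, "_cases")]] <-
      val("diagene", paste0("incident_", ep, "_cases")) +
      val("dcs", paste0("incident_", ep, "_cases"))
    for (cohort in c("diagene", "dcs")) {
      out[[paste0("prevalent_", ep, "_pct_", cohort)]] <-
        100 * val(cohort, paste0("prevalent_", ep, "_cases")) /
        val(cohort, "n_participants")
      out[[paste0("prevalent_", ep, "_pct_of_total_", cohort)]] <-
        100 * val(cohort, paste0("prevalent_", ep, "_cases")) /
        val(cohort, paste0("prevalent_", ep, "_total"))
      out[[paste0("incident_", ep, "_pct_", cohort)]] <-
        100 * val(cohort, paste0("incident_", ep, "_cases")) /
        val(cohort, paste0("incident_", ep, "_total"))
    }
  }
  for (cohort in c("diagene", "dcs")) {
    lip <- derive_non_hdl(data.frame(
      total_cholesterol = val(cohort, "total_cholesterol_mean"),
      hdl = val(cohort, "hdl_mean")))
    out[[paste0("non_hdl_mean_", cohort)]] <- lip$non_hdl
  }
  out
}
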