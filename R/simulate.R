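#' Default simulation configuration
#'
#' Two synthetic cohorts mirroring the published structure of the DiaGene
#' (n = 1815, mean follow-up 7.0 years) and Hoorn DCS (n = 1518, median
#' follow-up 8.5 years) type 2 diabetes cohorts: covariate means/SDs and
#' smoking mix from the published cohort table, complication prevalences
#' and incident rates from the printed case/total counts, 96-well plate
#' structure with pooled-plasma technical replicates (technical CV 5%,
#' matching the reported average derived-trait RSDs of 5.92% and 4.40%),
#' below 7% covariate missingness, and planted per-trait effects on the
#' outcomes covering positive, negative and null traits.
#'
#' @return nested configuration list; see the methods vignette for the
#'   meaning and units of every field.
#' @export
default_sim_config <- function() {
  list(
    cohorts = list(
      diagene = list(
        n = 1815L, age_mean = 65.2, age_sd = 10.6, female_frac = 0.463,
        onset_mean = 54.9, onset_sd = 11.7, bmi_mean = 29.5, bmi_sd = 5.5,
        hba1c_mean = 7.0, hba1c_sd = 1.1, sbp_mean = 141.9, sbp_sd = 18.8,
        tc_mean = 4.3, tc_sd = 0.9, hdl_mean = 1.2, hdl_sd = 0.3,
        smoking_probs = c(never = 425, former = 924, current = 294) / 1643,
        creatinine_mean = 80, creatinine_sd = 18,
        follow_up_median = 7.0, follow_up_iqr = 2.2,
        prevalence = c(cvd = 0.346, nephropathy = 0.202, retinopathy = 0.160),
        incident_rate = c(cvd = 0.101, nephropathy = 0.201,
                          retinopathy = 0.161)),
      dcs = list(
        n = 1518L, age_mean = 64.5, age_sd = 10.6, female_frac = 0.437,
        onset_mean = 57.3, onset_sd = 11.0, bmi_mean = 30.4, bmi_sd = 5.4,
        hba1c_mean = 6.8, hba1c_sd = 1.0, sbp_mean = 144, sbp_sd = 19,
        tc_mean = 4.6, tc_sd = 1.7, hdl_mean = 1.2, hdl_sd = 0.4,
        smoking_probs = c(never = 926, former = 334, current = 258) / 1518,
        creatinine_mean = 80, creatinine_sd = 18,
        follow_up_median = 8.5, follow_up_iqr = 1.8,
        prevalence = c(cvd = 0.190, nephropathy = 0.155, retinopathy = 0.142),
        incident_rate = c(cvd = 0.080, nephropathy = 0.124,
                          retinopathy = 0.099))),
    missing_rate = 0.03,
    plate_size = 80L, replicates_per_plate = 2L, plate_sd = 0.05,
    technical_cv = 0.05, low_intensity_rate = 0,
    total_intensity_meanlog = log(5e4), total_intensity_sdlog = 0.3,
    biological_sd = 0.35, factor_sd = c(1, 1, 0.8),
    covariate_effects = list(age = 0.03, female = -0.25),
    planted = list(
      prevalent = list(cvd = c(A2FS0B = 0.32, A3L = -0.18),
                       nephropathy = c(A3E = 0.25, A2FS0G = -0.20),
                       retinopathy = c(MHy = -0.24)),
      incident = list(cvd = c(A2FS0B = 0.10),
                      nephropathy = c(A2FGS = 0.16, A2FS0G = -0.21),
                      retinopathy = c(MHy = -0.20)))
  )
}

#' Baseline mean log-abundances of the packaged panel
#'
#' Deterministic heuristic profile: fully galactosylated, alpha2,6-
#' sialylated diantennary species dominate total plasma N-glycome spectra,
#' Man5 leads the high-mannose series, bisected and tetra-antennary
#' species are minor. A small count-derived jitter breaks ties.
#'
#' @keywords internal
glycome_mu <- function(panel) {
  an <- panel$annotation
  comp <- panel$composition
  cx <- an$glycan_class == "complex"
  mu <- numeric(nrow(comp))
  mu[an$glycan_class == "high-mannose"] <- 0.3
  mu[comp$label == "H5N2"] <- 1.2
  mu[an$glycan_class == "hybrid"] <- 0.2
  mu[cx & an$antennarity == 1L] <- -0.3
  mu[cx & an$antennarity == 2L] <- 1.2
  mu[cx & an$antennarity == 3L] <- 0.4
  mu[cx & an$antennarity == 4L] <- -0.4
  full_gal <- cx & an$galactoses == an$antennarity
  mu <- mu + 0.5 * full_gal + 0.2 * (comp$F >= 1L) - 0.6 * an$bisected +
    0.35 * (comp$E >= 1L) + 0.1 * comp$E - 0.15 * comp$L
  mu + 0.05 * ((comp$H * 7L + comp$N * 3L + comp$F + 2L * comp$L +
                  5L * comp$E) %% 7L - 3L)
}

#' Latent-factor loadings encoding trait-trait correlation
#'
#' Three biological factors reproduce the correlation structure reported
#' for plasma glycomes: bisection positively correlated with fucosylation
#' and negatively with galactosylation (factor 1), alpha2,6- versus
#' alpha2,3-sialylation trade-off (factor 2), and a branching factor
#' (factor 3).
#'
#' @keywords internal
glycome_loadings <- function(panel) {
  an <- panel$annotation
  comp <- panel$composition
  cx <- an$glycan_class == "complex"
  full_gal <- cx & an$galactoses == an$antennarity
  cbind(
    bisect_fucose = 0.35 * an$bisected + 0.15 * (comp$F >= 1L) -
      0.25 * full_gal,
    sialyl_linkage = 0.20 * comp$E - 0.20 * comp$L,
    branching = 0.20 * (an$antennarity >= 3L) - 0.10 * (an$antennarity == 2L)
  )
}

#' Simulate raw glycome spectra for one cohort
#'
#' Per clinical sample a latent log-abundance vector (heuristic mean
#' profile + correlated biological factors + independent noise) is mapped
#' through a softmax to compositional proportions (a logistic-normal
#' profile; rows sum to one by construction). Wells are laid out on plates
#' of `plate_size` clinical samples plus `replicates_per_plate` wells of a
#' single pooled-plasma profile. Measured intensities apply a per-plate
#' per-composition multiplicative shift (log-SD `plate_sd`), multiplicative
#' technical noise of coefficient of variation `technical_cv` to every
#' well, and a log-normal total spray intensity; optionally a fraction
#' `low_intensity_rate` of clinical wells is degraded to 1% intensity to
#' exercise the QC filter.
#'
#' @param panel annotated panel.
#' @param n number of clinical samples.
#' @param config configuration list, see [default_sim_config()].
#' @param seed integer seed; output is fully determined by it.
#' @param prefix sample-id prefix.
#' @return list: `raw` (wells x compositions intensity matrix), `info`
#'   (well metadata: sample_id, plate, is_replicate, replicate_group),
#'   `latent_prop` (clinical samples' noise-free proportions).
#' @export
simulate_glycome <- function(panel, n, config = default_sim_config(),
                             seed = 1L, prefix = "S") {
  set.seed(seed)
  ncomp <- nrow(panel$composition)
  mu <- glycome_mu(panel)
  L <- glycome_loadings(panel)
  fac <- matrix(stats::rnorm(n * ncol(L)), n) %*%
    diag(config$factor_sd, ncol(L))
  eta <- matrix(mu, n, ncomp, byrow = TRUE) + fac %*% t(L) +
    matrix(stats::rnorm(n * ncomp, sd = config$biological_sd), n, ncomp)
  latent <- exp(eta)
  latent <- latent / rowSums(latent)
  colnames(latent) <- panel$composition$label
  rownames(latent) <- sprintf("%s%04d", prefix, seq_len(n))

  nplate <- ceiling(n / config$plate_size)
  plate <- rep(seq_len(nplate), each = config$plate_size)[seq_len(n)]
  nrep <- nplate * config$replicates_per_plate
  pool_prop <- exp(mu) / sum(exp(mu))
  info <- data.frame(
    sample_id = c(rownames(latent),
                  sprintf("%sPOOL%03d", prefix, seq_len(nrep))),
    plate = c(plate, rep(seq_len(nplate), each = config$replicates_per_plate)),
    is_replicate = rep(c(FALSE, TRUE), c(n, nrep)),
    replicate_group = rep(c(NA_character_, "pool"), c(n, nrep)),
    stringsAsFactors = FALSE)

  prop <- rbind(latent, matrix(pool_prop, nrep, ncomp, byrow = TRUE))
  shift <- matrix(stats::rnorm(nplate * ncomp, sd = config$plate_sd),
                  nplate, ncomp)
  sdlog <- sqrt(log(1 + config$technical_cv^2))
  tech <- matrix(stats::rnorm(nrow(prop) * ncomp, sd = sdlog),
                 nrow(prop), ncomp)
  total <- stats::rlnorm(nrow(prop), config$total_intensity_meanlog,
                         config$total_intensity_sdlog)
  raw <- prop * exp(shift[info$plate, , drop = FALSE] + tech) * total
  if (config$low_intensity_rate > 0) {
    k <- round(config$low_intensity_rate * n)
    if (k > 0) {
      low <- sample(seq_len(n), k)
      raw[low, ] <- raw[low, ] * 0.01
    }
  }
  rownames(raw) <- info$sample_id
  colnames(raw) <- panel$composition$label
  list(raw = raw, info = info, latent_prop = latent)
}

#' Simulate baseline clinical covariates for one cohort
#'
#' Draws the covariate table from the published cohort means and SDs:
#' normal marginals for age, BMI, HbA1c, systolic blood pressure, total
#' and HDL cholesterol and creatinine (floored at plausible minima),
#' diabetes duration as age minus a drawn onset age (floored at 3 months),
#' and the smoking mix from the published category counts. The metabolic
#' covariates share a latent factor (positive loadings on BMI, blood
#' pressure, HbA1c, total cholesterol and creatinine, negative on HDL-c)
#' so that they are mutually predictive, as in real cohorts, while the
#' marginal SDs stay at their published values.
#'
#' @param cohort one cohort entry of the configuration.
#' @param seed integer seed.
#' @param prefix sample-id prefix.
#' @return data.frame of complete covariates (missingness is applied
#'   separately by [apply_missingness()]).
#' @export
simulate_covariates <- function(cohort, seed = 1L, prefix = "S") {
  set.seed(seed)
  n <- cohort$n
  age <- pmax(stats::rnorm(n, cohort$age_mean, cohort$age_sd), 25)
  onset <- stats::rnorm(n, cohort$onset_mean, cohort$onset_sd)
  z <- stats::rnorm(n)  # shared metabolic factor, unit variance
  draw <- function(mean, sd, r, floor) {
    pmax(mean + sd * (r * z + sqrt(1 - r^2) * stats::rnorm(n)), floor)
  }
  data.frame(
    subject_id = sprintf("%s%04d", prefix, seq_len(n)),
    sex = ifelse(stats::runif(n) < cohort$female_frac, "female", "male"),
    age = age,
    bmi = draw(cohort$bmi_mean, cohort$bmi_sd, 0.60, 15),
    hba1c = draw(cohort$hba1c_mean, cohort$hba1c_sd, 0.45, 4),
    sbp = draw(cohort$sbp_mean, cohort$sbp_sd, 0.45, 80),
    total_cholesterol = draw(cohort$tc_mean, cohort$tc_sd, 0.40, 1.5),
    hdl = draw(cohort$hdl_mean, cohort$hdl_sd, -0.45, 0.4),
    diabetes_duration = pmax(age - onset, 0.25),
    smoking = sample(names(cohort$smoking_probs), n, replace = TRUE,
                     prob = cohort$smoking_probs),
    creatinine = draw(cohort$creatinine_mean, cohort$creatinine_sd, 0.30, 30),
    stringsAsFactors = FALSE)
}

#' Mask covariate cells missing completely at random
#'
#' @param covars covariate data.frame.
#' @param vars columns to mask.
#' @param rate per-cell missingness probability (default below the 7%
#'   bound of the emulated cohorts).
#' @param seed integer seed.
#' @return the data.frame with `NA`s planted.
#' @export
apply_missingness <- function(covars, vars = c("bmi", "hdl",
                                               "total_cholesterol", "sbp",
                                               "hba1c", "smoking",
                                               "diabetes_duration",
                                               "creatinine"),
                              rate = 0.03, seed = 1L) {
  set.seed(seed)
  for (v in vars) {
    covars[[v]][stats::runif(nrow(covars)) < rate] <- NA
  }
  covars
}

solve_intercept <- function(lp, target) {
  stats::uniroot(function(b0) mean(stats::plogis(b0 + lp)) - target,
                 interval = c(-15, 15), tol = 1e-10)$root
}

solve_base_hazard <- function(lp, censor, target) {
  f <- function(loglam) {
    mean(1 - exp(-exp(loglam + lp) * censor)) - target
  }
  exp(stats::uniroot(f, interval = c(-12, 3), tol = 1e-10)$root)
}

#' Simulate ACR trajectories consistent with nephropathy labels
#'
#' Cases receive either two consecutive moderate-microalbuminuria values
#' (at or above the sex-specific 2.5/3.5 mg/mmol threshold) among the
#' first three visits, or a single high value (>= 12.5/17.5); controls
#' stay strictly below the moderate threshold. With probability
#' `1 - agreement` a subject's trajectory is drawn from the opposite
#' pattern, decoupling the rule from the label.
#'
#' @param case logical vector of nephropathy labels.
#' @param sex character vector (`"male"`/`"female"`).
#' @param subject_id identifiers.
#' @param visits visits per subject (default 4).
#' @param agreement probability the trajectory matches the label.
#' @param seed integer seed.
#' @return long data.frame `subject_id, sex, visit, acr`.
#' @export
simulate_acr <- function(case, sex, subject_id, visits = 4L, agreement = 1,
                         seed = 1L) {
  set.seed(seed)
  n <- length(case)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    thr <- acr_thresholds(sex[i])
    draw_case <- isTRUE(case[i])
    if (stats::runif(1) > agreement) draw_case <- !draw_case
    base <- stats::rlnorm(visits, log(0.8), 0.5)
    acr <- pmin(base, 0.9 * thr["micro"])
    if (draw_case) {
      if (stats::runif(1) < 0.5) {
        at <- sample(seq_len(min(3L, visits) - 1L), 1L)
        acr[c(at, at + 1L)] <- thr["micro"] * stats::runif(2, 1, 3)
      } else {
        acr[sample(seq_len(visits), 1L)] <- thr["high"] * stats::runif(1, 1, 2)
      }
    }
    rows[[i]] <- data.frame(subject_id = subject_id[i], sex = sex[i],
                            visit = seq_len(visits), acr = unname(acr),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate prevalent and incident outcomes from computed traits
#'
#' Prevalent complications are drawn from a logistic model whose linear
#' predictor combines the planted per-SD trait effects with mild age and
#' sex effects, the intercept solved numerically so the expected
#' prevalence matches the cohort target. Incident events among
#' baseline-negative subjects follow an exponential hazard with the
#' planted log hazard ratios, administratively censored at a per-subject
#' follow-up drawn around the cohort's published median; the baseline
#' hazard is calibrated so the expected incident fraction matches the
#' published rate. ACR trajectories are generated so the nephropathy rule
#' reproduces the planted prevalent nephropathy label.
#'
#' @param cohort one cohort entry of the configuration.
#' @param config full configuration (planted effects, covariate effects).
#' @param traits_z Z-scaled trait matrix of the cohort's subjects.
#' @param covars complete covariate data.frame aligned with `traits_z`.
#' @param seed integer seed.
#' @param acr_agreement probability an ACR trajectory matches its label.
#' @return list: `records` (endpoint long table), `acr` (trajectories),
#'   `truth` (planted effects as endpoint/design/trait/beta).
#' @export
simulate_outcomes <- function(cohort, config, traits_z, covars, seed = 1L,
                              acr_agreement = 1) {
  set.seed(seed)
  n <- nrow(traits_z)
  stopifnot(nrow(covars) == n)
  ce <- config$covariate_effects
  lp_cov <- ce$age * (covars$age - mean(covars$age)) +
    ce$female * (covars$sex == "female")
  planted_lp <- function(planted, ep) {
    b <- planted[[ep]]
    if (is.null(b) || !length(b)) return(rep(0, n))
    missing_tr <- setdiff(names(b), colnames(traits_z))
    if (length(missing_tr)) {
      stop("planted effect on unknown trait ", missing_tr[1])
    }
    drop(traits_z[, names(b), drop = FALSE] %*% b)
  }
  records <- list()
  prevalent_label <- list()
  for (ep in c("cvd", "nephropathy", "retinopathy")) {
    lp <- lp_cov + planted_lp(config$planted$prevalent, ep)
    b0 <- solve_intercept(lp, cohort$prevalence[[ep]])
    prev <- stats::runif(n) < stats::plogis(b0 + lp)
    prevalent_label[[ep]] <- prev
    risk <- which(!prev)
    censor <- pmax(stats::rnorm(length(risk), cohort$follow_up_median,
                                cohort$follow_up_iqr / 1.349), 0.5)
    lp_h <- (lp_cov[risk] +
               planted_lp(config$planted$incident, ep)[risk])
    target <- cohort$incident_rate[[ep]]
    lam0 <- tryCatch(solve_base_hazard(lp_h, censor, target),
                     error = function(e) {
                       warning("incident rate target ", target, " for ", ep,
                               " unreachable; using boundary hazard")
                       exp(3)
                     })
    etime <- stats::rexp(length(risk), rate = lam0 * exp(lp_h))
    event <- etime <= censor
    years <- numeric(n)
    ev <- logical(n)
    years[risk] <- pmin(etime, censor)
    ev[risk] <- event
    records[[ep]] <- data.frame(
      subject_id = covars$subject_id, endpoint = ep, prevalent = prev,
      event = ev, event_years = years, stringsAsFactors = FALSE)
  }
  acr <- simulate_acr(prevalent_label$nephropathy, covars$sex,
                      covars$subject_id, agreement = acr_agreement,
                      seed = seed + 7L)
  truth <- do.call(rbind, lapply(c("prevalent", "incident"), function(d) {
    do.call(rbind, lapply(names(config$planted[[d]]), function(ep) {
      b <- config$planted[[d]][[ep]]
      if (!length(b)) return(NULL)
      data.frame(endpoint = ep,
                 design = if (d == "prevalent") "prevalent-logistic"
                          else "incident-cox",
                 trait = names(b), beta = unname(b),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(records = do.call(rbind, records), acr = acr, truth = truth)
}

#' Simulate one full synthetic cohort
#'
#' Chains the glycome, covariate and outcome generators: raw plate-
#' structured spectra with pooled replicates, complete covariates, then
#' outcomes generated from the traits computed on the noise-free latent
#' profiles (the biological signal), and finally MCAR covariate
#' missingness. All randomness derives from `seed`.
#'
#' @param cohort_name `"diagene"` or `"dcs"` (any name present in
#'   `config$cohorts`).
#' @param config configuration list.
#' @param seed integer seed.
#' @param panel,defs annotated panel and trait definitions (packaged
#'   defaults).
#' @return list with `raw`, `info`, `latent_prop`, `covariates`
#'   (with missingness), `covariates_complete`, `records`, `acr`, `truth`.
#' @export
simulate_cohort <- function(cohort_name, config = default_sim_config(),
                            seed = 1L,
                            panel = read_glycan_panel(tpng_panel_file()),
                            defs = read_trait_panel(panel = panel)) {
  cohort <- config$cohorts[[cohort_name]]
  if (is.null(cohort)) stop("unknown cohort '", cohort_name, "'")
  prefix <- toupper(substr(cohort_name, 1, 1))
  gly <- simulate_glycome(panel, cohort$n, config, seed = seed,
                          prefix = prefix)
  covars <- simulate_covariates(cohort, seed = seed + 1L, prefix = prefix)
  latent_traits <- zscale(compute_traits(gly$latent_prop, defs, panel))
  out <- simulate_outcomes(cohort, config, latent_traits, covars,
                           seed = seed + 2L)
  covars_missing <- apply_missingness(covars, rate = config$missing_rate,
                                      seed = seed + 3L)
  list(raw = gly$raw, info = gly$info, latent_prop = gly$latent_prop,
       covariates = covars_missing, covariates_complete = covars,
       records = out$records, acr = out$acr, truth = out$truth,
       cohort = cohort_name)
}
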