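# Small covariate/trait fixtures for the association layer.
assoc_fx <- function(n = 500, seed = 1) {
  cfg <- default_sim_config()
  cfg$cohorts$diagene$n <- n
  covars <- simulate_covariates(cfg$cohorts$diagene, seed = seed)
  covars <- suppressWarnings(derive_non_hdl(covars))
  set.seed(seed + 1)
  traits <- matrix(rnorm(n * 3), n,
                   dimnames = list(covars$subject_id, c("t1", "t2", "t3")))
  list(covars = covars, traits = zscale(traits))
}

test_that("model 1 covariates are nested in the full model", {
  m1 <- covariate_set("model1", "nephropathy")
  full_nep <- covariate_set("full", "nephropathy")
  full_cvd <- covariate_set("full", "cvd")
  expect_true(all(m1 %in% full_nep))
  expect_false("creatinine" %in% full_nep)
  expect_true(all(c("creatinine", "smoking") %in% full_cvd))
  expect_true("creatinine" %in% covariate_set("full", "retinopathy"))
})

test_that("negating a trait negates its log odds ratio exactly", {
  fx <- assoc_fx()
  set.seed(3)
  y <- runif(500) < plogis(-1 + 0.4 * fx$traits[, "t1"])
  a <- fit_logistic(fx$traits, fx$covars, y, "model1", "cvd")
  neg <- fx$traits
  neg[, "t1"] <- -neg[, "t1"]
  b <- fit_logistic(neg, fx$covars, y, "model1", "cvd")
  expect_equal(a$beta[a$trait == "t1"], -b$beta[b$trait == "t1"])
  expect_equal(a$se, b$se)
  # repeated identical fits are bit-stable
  expect_identical(a, fit_logistic(fx$traits, fx$covars, y, "model1", "cvd"))
})

test_that("null logistic p values are uniform", {
  cfg <- default_sim_config()
  cfg$cohorts$diagene$n <- 2000L
  covars <- simulate_covariates(cfg$cohorts$diagene, seed = 5)
  pvals <- numeric(500)
  set.seed(6)
  for (r in seq_len(500)) {
    tr <- matrix(rnorm(2000), dimnames = list(covars$subject_id, "t"))
    y <- runif(2000) < 0.27
    pvals[r] <- fit_logistic(tr, covars, y, "model1", "cvd")$p
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("a planted per-SD log odds ratio is recovered without bias", {
  cfg <- default_sim_config()
  cfg$cohorts$diagene$n <- 3333L
  covars <- simulate_covariates(cfg$cohorts$diagene, seed = 8)
  reps <- 60
  est <- numeric(reps)
  set.seed(9)
  for (r in seq_len(reps)) {
    tr <- matrix(rnorm(3333), dimnames = list(covars$subject_id, "t"))
    lp <- 0.32 * tr[, 1]
    b0 <- uniroot(function(b) mean(plogis(b + lp)) - 0.27, c(-5, 5))$root
    y <- runif(3333) < plogis(b0 + lp)
    est[r] <- fit_logistic(tr, covars, y, "model1", "cvd")$beta
  }
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 0.32), 3.5 * mc_se + 0.32 * 0.02)
  expect_equal(exp(mean(est)), 1.38, tolerance = 0.02)
})

test_that("separation is flagged rather than reported as a p value", {
  fx <- assoc_fx(n = 120, seed = 21)
  y <- fx$traits[, "t1"] > 0  # perfectly separable
  res <- fit_logistic(fx$traits, fx$covars, y, "model1", "cvd")
  expect_true(res$flagged[res$trait == "t1"])
  expect_true(is.na(res$p[res$trait == "t1"]))
})

test_that("Cox fits are null-centered, recover planted hazards, and handle ties", {
  cfg <- default_sim_config()
  cfg$cohorts$diagene$n <- 2500L
  covars <- simulate_covariates(cfg$cohorts$diagene, seed = 31)
  reps <- 120
  est_null <- numeric(reps)
  est_plant <- numeric(reps)
  set.seed(32)
  for (r in seq_len(reps)) {
    tr <- matrix(rnorm(2500), dimnames = list(covars$subject_id, "t"))
    # exponential survival, ~20% events under administrative censoring
    haz_null <- 0.03
    t_ev <- rexp(2500, haz_null)
    cens <- runif(2500, 5, 9)
    est_null[r] <- fit_cox(tr, covars, t_ev <= cens, pmin(t_ev, cens),
                           "model1", "cvd")$beta
    t_ev2 <- rexp(2500, haz_null * exp(0.3 * tr[, 1]))
    est_plant[r] <- fit_cox(tr, covars, t_ev2 <= cens, pmin(t_ev2, cens),
                            "model1", "cvd")$beta
  }
  expect_lt(abs(mean(est_null)), 3.5 * sd(est_null) / sqrt(reps))
  # bias below 5% of the planted log hazard ratio
  expect_lt(abs(mean(est_plant) - 0.3), 0.05 * 0.3)
})

test_that("Efron and Breslow coincide on tie-free data", {
  fx <- assoc_fx(n = 300, seed = 41)
  set.seed(42)
  t_ev <- rexp(300, 0.05 * exp(0.2 * fx$traits[, "t1"]))
  cens <- runif(300, 2, 30)
  ev <- t_ev <= cens
  tt <- pmin(t_ev, cens)
  stopifnot(!anyDuplicated(tt[ev]))
  a <- fit_cox(fx$traits, fx$covars, ev, tt, "model1", "cvd", ties = "efron")
  b <- fit_cox(fx$traits, fx$covars, ev, tt, "model1", "cvd", ties = "breslow")
  expect_equal(a$beta, b$beta, tolerance = 1e-10)
  expect_equal(a$se, b$se, tolerance = 1e-10)
})

test_that("Rubin pooling collapses to the single fit for identical imputations", {
  fx <- assoc_fx(n = 200, seed = 51)
  set.seed(52)
  y <- runif(200) < 0.3
  one <- fit_logistic(fx$traits, fx$covars, y, "model1", "cvd")
  pooled <- pool_rubin(list(one, one, one))
  expect_equal(pooled$beta, one$beta)
  expect_equal(pooled$se, one$se, tolerance = 1e-12)
  expect_equal(pooled$p, one$p, tolerance = 1e-12)
})
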