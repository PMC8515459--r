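#' Covariate sets of the two adjustment models
#'
#' Model 1 (basic) adjusts for age, sex and their interaction. The full
#' model adds BMI, HDL-c, non-HDL-c, systolic blood pressure, diabetes
#' duration, HbA1c and smoking (two indicators, never = reference);
#' creatinine is additionally included for the CVD and retinopathy
#' endpoints (not nephropathy).
#'
#' @param model `"model1"` or `"full"`.
#' @param endpoint `"cvd"`, `"nephropathy"` or `"retinopathy"`.
#' @return character vector of covariate column names.
#' @export
covariate_set <- function(model = c("model1", "full"),
                          endpoint = c("cvd", "nephropathy", "retinopathy")) {
  model <- match.arg(model)
  endpoint <- match.arg(endpoint)
  base <- c("age", "sex", "age:sex")
  if (model == "model1") return(base)
  full <- c(base, "bmi", "hdl", "non_hdl", "sbp", "diabetes_duration",
            "hba1c", "smoking")
  if (endpoint %in% c("cvd", "retinopathy")) full <- c(full, "creatinine")
  full
}

#' Build the covariate design matrix (no intercept column)
#' @keywords internal
build_design <- function(covars, model, endpoint) {
  vars <- covariate_set(model, endpoint)
  sex <- as.numeric(covars$sex == "female")
  X <- cbind(age = covars$age, sex = sex, `age:sex` = covars$age * sex)
  if ("smoking" %in% vars) {
    smoking <- as.character(covars$smoking)
    X <- cbind(X,
               bmi = covars$bmi, hdl = covars$hdl, non_hdl = covars$non_hdl,
               sbp = covars$sbp, diabetes_duration = covars$diabetes_duration,
               hba1c = covars$hba1c,
               smoking_former = as.numeric(smoking == "former"),
               smoking_current = as.numeric(smoking == "current"))
    if ("creatinine" %in% vars) X <- cbind(X, creatinine = covars$creatinine)
  }
  if (anyNA(X)) stop("covariates contain missing values; impute first")
  sds <- apply(X, 2, stats::sd)
  if (any(sds < 1e-12)) {
    stop("zero-variance covariate: ", colnames(X)[sds < 1e-12][1])
  }
  X
}

logistic_wald <- function(X, y, max_abs_beta = 15) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 50L)))
  beta <- fit$coefficients
  flagged <- !fit$converged || any(abs(beta) > max_abs_beta)
  w <- fit$weights
  info <- crossprod(X * sqrt(w))
  se <- tryCatch(sqrt(diag(chol2inv(chol(info)))),
                 error = function(e) rep(NA_real_, ncol(X)))
  list(beta = beta, se = se, flagged = flagged)
}

#' Per-trait logistic regression for prevalent outcomes
#'
#' One model per trait: outcome ~ trait + covariates, fitted by iteratively
#' reweighted least squares (deviance tolerance 1e-8, at most 50
#' iterations). The effect estimate is the odds ratio per 1 SD of the
#' Z-scaled trait with a Wald p value. Separation (non-convergence or a
#' diverging trait coefficient) flags the result and leaves p missing.
#' Samples with a missing trait value are dropped pairwise.
#'
#' @param traits samples x traits Z-scaled matrix.
#' @param covars data.frame of complete covariates (post-imputation),
#'   aligned with `traits` rows.
#' @param outcome logical/0-1 vector.
#' @param model,endpoint select the covariate set, see [covariate_set()].
#' @return data.frame: trait, beta, se, effect, p, n, events, flagged.
#' @export
fit_logistic <- function(traits, covars, outcome,
                         model = "model1", endpoint = "cvd") {
  stopifnot(nrow(traits) == length(outcome), nrow(covars) == length(outcome))
  y <- as.numeric(outcome)
  Xbase <- build_design(covars, model, endpoint)
  res <- lapply(colnames(traits), function(tr) {
    v <- traits[, tr]
    ok <- !is.na(v) & !is.na(y)
    X <- cbind(1, trait = v[ok], Xbase[ok, , drop = FALSE])
    f <- logistic_wald(X, y[ok])
    b <- f$beta[2]; se <- f$se[2]
    p <- if (f$flagged || is.na(se)) NA_real_ else
      2 * stats::pnorm(-abs(b / se))
    data.frame(trait = tr, beta = b, se = se, effect = exp(b), p = p,
               n = sum(ok), events = sum(y[ok]), flagged = f$flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-trait Cox proportional hazards regression for incident outcomes
#'
#' One model per trait on the baseline-negative risk set, fitted by Newton
#' optimization of the partial likelihood with Efron tie handling
#' (`survival::coxph`). The effect is the hazard ratio per 1 SD of the
#' Z-scaled trait. Monotone likelihood (infinite coefficient warnings)
#' flags the result.
#'
#' @param traits,covars as in [fit_logistic()].
#' @param event logical event indicator; at least 10 events required.
#' @param time positive follow-up time (years).
#' @param model,endpoint select the covariate set.
#' @param ties tie-handling method passed to `coxph` (default `"efron"`).
#' @return data.frame: trait, beta, se, effect, p, n, events, flagged.
#' @export
fit_cox <- function(traits, covars, event, time,
                    model = "model1", endpoint = "cvd", ties = "efron") {
  stopifnot(nrow(traits) == length(event), length(time) == length(event))
  if (sum(event) == 0L) stop("no events in the incident risk set")
  if (sum(event) < 10L) {
    warning("fewer than 10 events; Cox estimates will be unstable")
  }
  if (any(time <= 0)) stop("non-positive follow-up times in the risk set")
  Xbase <- build_design(covars, model, endpoint)
  surv <- survival::Surv(time, as.numeric(event))
  res <- lapply(colnames(traits), function(tr) {
    v <- traits[, tr]
    ok <- !is.na(v)
    X <- cbind(trait = v[ok], Xbase[ok, , drop = FALSE])
    flagged <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(surv[ok] ~ X, ties = ties),
      warning = function(w) {
        if (grepl("infinite|converge", conditionMessage(w))) flagged <<- TRUE
        invokeRestart("muffleWarning")
      })
    b <- fit$coefficients[1]
    se <- sqrt(diag(fit$var))[1]
    p <- if (flagged) NA_real_ else 2 * stats::pnorm(-abs(b / se))
    data.frame(trait = tr, beta = unname(b), se = unname(se),
               effect = exp(unname(b)), p = p, n = sum(ok),
               events = sum(event[ok]), flagged = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pool per-trait fits across imputed datasets (Rubin's rules)
#'
#' Combines the m per-trait fits obtained on m completed covariate tables:
#' pooled estimate = mean of estimates, total variance = within + (1 +
#' 1/m) between, p value from a t reference with the classical
#' degrees-of-freedom formula. With identical fits (zero between-imputation
#' variance) the pooled result equals the single-dataset result.
#'
#' @param fits list of data.frames from [fit_logistic()] / [fit_cox()].
#' @return pooled data.frame of the same shape.
#' @export
pool_rubin <- function(fits) {
  m <- length(fits)
  if (m == 1L) return(fits[[1]])
  out <- fits[[1]]
  for (i in seq_len(nrow(out))) {
    betas <- vapply(fits, function(f) f$beta[i], numeric(1))
    ses <- vapply(fits, function(f) f$se[i], numeric(1))
    qbar <- mean(betas)
    W <- mean(ses^2)
    B <- stats::var(betas)
    Tvar <- W + (1 + 1 / m) * B
    se <- sqrt(Tvar)
    if (B < 1e-14) {
      p <- 2 * stats::pnorm(-abs(qbar / se))
    } else {
      nu <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
      p <- 2 * stats::pt(-abs(qbar / se), df = nu)
    }
    out$beta[i] <- qbar
    out$se[i] <- se
    out$effect[i] <- exp(qbar)
    out$p[i] <- p
    out$flagged[i] <- any(vapply(fits, function(f) f$flagged[i], logical(1)))
  }
  out
}
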