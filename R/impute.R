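#' Derive non-HDL cholesterol
#'
#' Non-HDL-c = total cholesterol minus HDL-c, filled only where both inputs
#' are observed; negative results are kept (they indicate a data error) but
#' recorded in the `warnings` attribute.
#'
#' @param table data.frame with `total_cholesterol` and `hdl` columns
#'   (mmol/L); a `non_hdl` column is created or completed.
#' @return the table with `non_hdl` filled; attribute `warnings` lists
#'   subjects with negative derived values.
#' @export
derive_non_hdl <- function(table) {
  stopifnot(all(c("total_cholesterol", "hdl") %in% names(table)))
  if (!"non_hdl" %in% names(table)) table$non_hdl <- NA_real_
  fill <- is.na(table$non_hdl) & !is.na(table$total_cholesterol) &
    !is.na(table$hdl)
  table$non_hdl[fill] <- table$total_cholesterol[fill] - table$hdl[fill]
  neg <- which(!is.na(table$non_hdl) & table$non_hdl < 0)
  warn <- data.frame(row = neg, value = table$non_hdl[neg])
  if (length(neg)) {
    warning(length(neg), " subjects with negative non-HDL-c (kept; check ",
            "cholesterol inputs)")
  }
  attr(table, "warnings") <- warn
  table
}

pmm_draw <- function(y_obs, X_obs, X_mis, donors = 5L, ridge = 1e-5) {
  p <- ncol(X_obs)
  XtX <- crossprod(X_obs) + diag(ridge, p)
  Xty <- crossprod(X_obs, y_obs)
  R <- chol(XtX)
  beta_hat <- backsolve(R, forwardsolve(t(R), Xty))
  res <- y_obs - X_obs %*% beta_hat
  df <- max(length(y_obs) - p, 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1L, df)
  beta_star <- beta_hat +
    backsolve(R, stats::rnorm(p)) * sqrt(sigma2 * df / max(sum(res^2), 1e-12))
  pred_obs <- drop(X_obs %*% beta_hat)
  pred_mis <- drop(X_mis %*% beta_star)
  vapply(pred_mis, function(pm) {
    d <- abs(pred_obs - pm)
    pool <- order(d)[seq_len(min(donors, length(d)))]
    y_obs[sample(pool, 1L)]
  }, numeric(1))
}

#' Chained-equations imputation of clinical covariates
#'
#' Multivariate imputation by chained equations: continuous covariates are
#' imputed by predictive mean matching (Bayesian parameter draw, nearest
#' `donors` observed predictions), categorical covariates (smoking) by a
#' draw from a multinomial logistic fit. Observed cells are never modified;
#' glycan traits and endpoints are never imputed. The `m` completed tables
#' are generated from independent chains; the whole procedure is
#' deterministic given `seed`.
#'
#' @param table data.frame of covariates.
#' @param vars variables to impute (default: every column with missing
#'   values). Character/factor columns are imputed multinomially.
#' @param predictors variables used as predictors (default: all `vars` plus
#'   every complete numeric column, e.g. auxiliary measurements from
#'   adjacent years).
#' @param m number of completed tables (default 5).
#' @param maxit chained-equation iterations per table (default 10).
#' @param donors PMM donor pool size (default 5).
#' @param seed integer seed.
#' @return list of `m` completed data.frames.
#' @export
mice_impute <- function(table, vars = NULL, predictors = NULL, m = 5L,
                        maxit = 10L, donors = 5L, seed = 1L) {
  miss_count <- vapply(table, function(v) sum(is.na(v)), integer(1))
  if (is.null(vars)) vars <- names(table)[miss_count > 0L]
  if (any(miss_count[vars] / nrow(table) >= 0.5)) {
    stop("variable '", vars[which.max(miss_count[vars])],
         "' has >= 50% missing values")
  }
  if (!length(vars) || all(miss_count[vars] == 0L)) {
    return(replicate(m, table, simplify = FALSE))
  }
  if (is.null(predictors)) {
    complete_num <- names(table)[miss_count == 0L &
      vapply(table, is.numeric, logical(1))]
    predictors <- union(vars, complete_num)
  }
  vars <- vars[order(miss_count[vars])]
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  lapply(seq_len(m), function(chain) {
    filled <- table
    for (v in vars) {  # initialize by sampling observed values
      mis <- is.na(filled[[v]])
      filled[[v]][mis] <- sample(filled[[v]][!mis], sum(mis), replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (v in vars) {
        mis <- is.na(table[[v]])
        if (!any(mis)) next
        rhs <- setdiff(predictors, v)
        if (is.numeric(table[[v]])) {
          X <- stats::model.matrix(~ ., data = filled[, rhs, drop = FALSE])
          filled[[v]][mis] <- pmm_draw(filled[[v]][!mis],
                                       X[!mis, , drop = FALSE],
                                       X[mis, , drop = FALSE], donors)
        } else {
          dat <- filled[, rhs, drop = FALSE]
          dat$.y <- factor(filled[[v]])
          fit <- nnet::multinom(.y ~ ., data = dat[!mis, , drop = FALSE],
                                trace = FALSE)
          pr <- stats::predict(fit, newdata = dat[mis, , drop = FALSE],
                               type = "probs")
          pr <- matrix(pr, nrow = sum(mis))
          lev <- fit$lev
          if (ncol(pr) == 1L) pr <- cbind(1 - pr, pr)  # two-level outcome
          draw <- apply(pr, 1, function(p) sample(lev, 1L, prob = p))
          filled[[v]][mis] <- draw
        }
      }
    }
    filled
  })
}
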