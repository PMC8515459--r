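#' Quality-control filter on raw spectra
#'
#' Removes mass spectra with low total intensity before normalization
#' (quality control runs on raw spectra, normalization after). The default
#' threshold is 10% of the median row sum, since absolute intensity scales
#' are instrument dependent.
#'
#' @param raw samples x compositions nonnegative intensity matrix.
#' @param min_total_intensity absolute intensity threshold; if `NULL`,
#'   `relative_threshold` times the median row sum is used.
#' @param relative_threshold fraction of the median row sum (default 0.1).
#' @return list with `raw` (retained rows) and `exclusions`, a data.frame
#'   `sample_id, reason, value`.
#' @export
qc_filter <- function(raw, min_total_intensity = NULL,
                      relative_threshold = 0.1) {
  stopifnot(all(raw >= 0))
  totals <- rowSums(raw)
  if (is.null(min_total_intensity)) {
    min_total_intensity <- relative_threshold * stats::median(totals)
  }
  stopifnot(min_total_intensity >= 0)
  low <- totals < min_total_intensity
  if (all(low)) {
    stop("QC threshold ", format(min_total_intensity),
         " excludes every sample")
  }
  exclusions <- data.frame(sample_id = rownames(raw)[low],
                           reason = rep("low_total_intensity", sum(low)),
                           value = unname(totals[low]), row.names = NULL,
                           stringsAsFactors = FALSE)
  list(raw = raw[!low, , drop = FALSE], exclusions = exclusions)
}

#' Total-area normalization
#'
#' Divides every spectrum by its intensity sum so that each sample's
#' composition abundances sum to one. All-zero rows cannot be normalized;
#' they are dropped and reported in the `exclusions` attribute.
#'
#' @param raw samples x compositions nonnegative matrix.
#' @return row-normalized matrix; attribute `exclusions` records dropped
#'   all-zero rows.
#' @export
total_area_normalize <- function(raw) {
  stopifnot(all(raw >= 0))
  totals <- rowSums(raw)
  zero <- totals == 0
  excl <- data.frame(sample_id = rownames(raw)[zero],
                     reason = rep("zero_total", sum(zero)),
                     value = numeric(sum(zero)), row.names = NULL,
                     stringsAsFactors = FALSE)
  if (any(zero)) {
    warning(sum(zero), " all-zero spectra dropped during normalization")
  }
  out <- raw[!zero, , drop = FALSE] / totals[!zero]
  attr(out, "exclusions") <- excl
  out
}

#' Technical precision from pooled-plasma replicates
#'
#' Relative standard deviation (percent, n - 1 SD) of each trait across
#' technical replicates of the same pooled material, plus the average over
#' traits. With several replicate groups the per-trait RSD is the mean over
#' groups with at least two members.
#'
#' @param traits samples x traits matrix (derived traits or normalized
#'   direct compositions).
#' @param groups replicate-group label per row; `NA` rows (clinical
#'   samples) are ignored.
#' @return list with `per_trait` (named RSD vector, percent) and `mean_rsd`.
#' @export
replicate_rsd <- function(traits, groups) {
  stopifnot(nrow(traits) == length(groups))
  keep <- !is.na(groups)
  tab <- table(groups[keep])
  use <- names(tab)[tab >= 2L]
  if (!length(use)) stop("no replicate group with >= 2 members")
  per_group <- sapply(use, function(g) {
    x <- traits[keep & groups == g, , drop = FALSE]
    100 * apply(x, 2, stats::sd) / abs(colMeans(x))
  })
  per_trait <- rowMeans(as.matrix(per_group), na.rm = TRUE)
  names(per_trait) <- colnames(traits)
  list(per_trait = per_trait, mean_rsd = mean(per_trait, na.rm = TRUE))
}

eb_prior_a <- function(delta_hat) {
  m <- mean(delta_hat); s2 <- stats::var(delta_hat)
  (2 * s2 + m^2) / s2
}
eb_prior_b <- function(delta_hat) {
  m <- mean(delta_hat); s2 <- stats::var(delta_hat)
  (m * s2 + m^3) / s2
}

#' Empirical-Bayes batch correction
#'
#' Parametric location-scale harmonization of plate/batch effects:
#' each feature is standardized against its grand mean and pooled variance,
#' per-batch location and scale parameters are estimated and shrunk toward
#' common normal / inverse-gamma priors fitted across features by the
#' method of moments, and the data are transformed back. No covariate
#' preservation term is used.
#'
#' @param x samples x features matrix (derived traits by default in this
#'   pipeline; direct compositions also work).
#' @param batch batch/plate label per row; every batch needs >= 2 samples.
#' @param eb logical; `FALSE` uses the unshrunk per-batch estimates.
#' @param tol,maxit convergence control of the fixed-point shrinkage
#'   iteration.
#' @return corrected matrix of the same shape.
#' @export
batch_correct <- function(x, batch, eb = TRUE, tol = 1e-8, maxit = 200L) {
  x <- as.matrix(x)
  batch <- as.character(batch)
  stopifnot(nrow(x) == length(batch), ncol(x) >= 2L)
  sizes <- table(batch)
  if (length(sizes) < 2L) stop("batch correction needs >= 2 batches")
  if (any(sizes < 2L)) {
    stop("singleton batch '", names(sizes)[sizes < 2L][1],
         "': merge it with a neighbouring plate before correction")
  }
  batches <- names(sizes)
  n <- nrow(x); p <- ncol(x)
  bmean <- do.call(rbind, lapply(batches, function(b) {
    colMeans(x[batch == b, , drop = FALSE])
  }))
  rownames(bmean) <- batches
  grand <- as.numeric(crossprod(as.numeric(sizes[batches]) / n, bmean))
  resid <- x - bmean[batch, , drop = FALSE]
  var_pooled <- colSums(resid^2) / n
  if (any(var_pooled < 1e-12)) {
    stop("feature ", colnames(x)[var_pooled < 1e-12][1],
         " has (near) zero pooled variance")
  }
  z <- sweep(sweep(x, 2, grand), 2, sqrt(var_pooled), "/")
  out <- z
  for (b in batches) {
    rows <- batch == b
    nb <- sum(rows)
    zb <- z[rows, , drop = FALSE]
    gamma_hat <- colMeans(zb)
    delta_hat <- apply(zb, 2, stats::var)
    if (eb) {
      g_bar <- mean(gamma_hat); t2 <- stats::var(gamma_hat)
      a <- eb_prior_a(delta_hat); bp <- eb_prior_b(delta_hat)
      gamma_star <- gamma_hat
      delta_star <- delta_hat
      for (it in seq_len(maxit)) {
        g_new <- (nb * t2 * gamma_hat + delta_star * g_bar) /
          (nb * t2 + delta_star)
        ss <- colSums((zb - matrix(g_new, nb, p, byrow = TRUE))^2)
        d_new <- (bp + 0.5 * ss) / (nb / 2 + a - 1)
        change <- max(abs(g_new - gamma_star) / (abs(gamma_star) + 1e-12),
                      abs(d_new - delta_star) / delta_star)
        gamma_star <- g_new
        delta_star <- d_new
        if (change < tol) break
      }
    } else {
      gamma_star <- gamma_hat
      delta_star <- delta_hat
    }
    out[rows, ] <- sweep(sweep(zb, 2, gamma_star), 2, sqrt(delta_star), "/")
  }
  sweep(sweep(out, 2, sqrt(var_pooled), "*"), 2, grand, "+")
}
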