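#' Evaluate a structural selector expression over an annotated panel
#'
#' Selector expressions are conjunctions of keywords separated by `&`:
#' class keywords `highman`, `hybrid`, `complex`, `all`; antennarity `A1`
#' to `A4`; bisection `B` / `B0`; fucosylation `F` (F >= 1) / `F0`;
#' sialylation `S` / `S0` (L + E), `E` / `E0`, `L` / `L0`; galactosylation
#' `G` (>= 1) / `G0`.
#'
#' @param expr selector string, e.g. `"complex&A2&F&S0"`.
#' @param panel list from [read_glycan_panel()].
#' @return logical vector over panel compositions.
#' @export
selector_mask <- function(expr, panel) {
  comp <- panel$composition
  an <- panel$annotation
  mask <- rep(TRUE, nrow(comp))
  for (tok in trimws(strsplit(expr, "&", fixed = TRUE)[[1]])) {
    m <- switch(tok,
      all = rep(TRUE, nrow(comp)),
      highman = an$glycan_class == "high-mannose",
      hybrid = an$glycan_class == "hybrid",
      complex = an$glycan_class == "complex",
      A1 = an$antennarity == 1L,
      A2 = an$antennarity == 2L,
      A3 = an$antennarity == 3L,
      A4 = an$antennarity == 4L,
      B = an$bisected,
      B0 = !an$bisected,
      F = comp$F >= 1L,
      F0 = comp$F == 0L,
      S = comp$L + comp$E >= 1L,
      S0 = comp$L + comp$E == 0L,
      E = comp$E >= 1L,
      E0 = comp$E == 0L,
      L = comp$L >= 1L,
      L0 = comp$L == 0L,
      G = an$galactoses >= 1L,
      G0 = an$galactoses == 0L,
      stop("unknown selector keyword '", tok, "' in '", expr, "'")
    )
    mask <- mask & m
  }
  mask
}

feature_counts <- function(feature, panel) {
  comp <- panel$composition
  switch(feature,
    E = comp$E,
    L = comp$L,
    S = comp$L + comp$E,
    G = panel$annotation$galactoses,
    stop("feature '", feature, "' is not a count; per-antenna and ",
         "per-galactose traits need one of E, L, S, G")
  )
}

#' Load a derived-trait specification
#'
#' Reads a trait TSV with columns `name`, `scope`, `feature`, `weighting`
#' (one of `fraction`, `per-antenna`, `per-galactose`, `ratio`) and an
#' optional `description`, and validates each definition against the panel:
#' names must be unique, weightings known, selector keywords known, and
#' every scope must select at least one packaged composition.
#'
#' @param path trait TSV path (defaults to the packaged 45-trait spec).
#' @param panel annotated panel from [read_glycan_panel()].
#' @return data.frame of validated trait definitions.
#' @export
read_trait_panel <- function(path = tpng_trait_file(),
                             panel = read_glycan_panel(tpng_panel_file())) {
  defs <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "scope", "feature", "weighting")
  if (!all(need %in% names(defs))) {
    stop("trait spec ", path, " must have columns ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(defs$name)) {
    stop("duplicate trait name '", defs$name[duplicated(defs$name)][1],
         "' in ", path)
  }
  bad <- setdiff(defs$weighting, c("fraction", "per-antenna", "per-galactose",
                                   "ratio"))
  if (length(bad)) stop("unknown weighting '", bad[1], "' in ", path)
  for (i in seq_len(nrow(defs))) {
    sc <- selector_mask(defs$scope[i], panel)
    if (!any(sc)) {
      stop("trait ", defs$name[i], ": scope '", defs$scope[i],
           "' selects no packaged composition")
    }
    if (defs$weighting[i] %in% c("fraction", "ratio")) {
      selector_mask(defs$feature[i], panel)  # validates keywords
    } else {
      feature_counts(defs$feature[i], panel)
    }
  }
  if (!"description" %in% names(defs)) defs$description <- defs$name
  defs
}

#' Numerator/denominator weights of each trait over the panel
#'
#' @keywords internal
trait_weights <- function(defs, panel) {
  ncomp <- nrow(panel$composition)
  wnum <- matrix(0, ncomp, nrow(defs),
                 dimnames = list(panel$composition$label, defs$name))
  wden <- wnum
  for (i in seq_len(nrow(defs))) {
    sc <- selector_mask(defs$scope[i], panel)
    switch(defs$weighting[i],
      fraction = {
        wnum[sc & selector_mask(defs$feature[i], panel), i] <- 1
        wden[sc, i] <- 1
      },
      ratio = {
        wnum[selector_mask(defs$feature[i], panel), i] <- 1
        wden[sc, i] <- 1
      },
      "per-antenna" = {
        cnt <- feature_counts(defs$feature[i], panel)
        wnum[sc, i] <- cnt[sc]
        wden[sc, i] <- panel$annotation$antennarity[sc]
      },
      "per-galactose" = {
        cnt <- feature_counts(defs$feature[i], panel)
        wnum[sc, i] <- cnt[sc]
        wden[sc, i] <- panel$annotation$galactoses[sc]
      }
    )
  }
  list(num = wnum, den = wden)
}

#' Compute derived glycosylation traits
#'
#' Derived traits summarize one structural feature as a ratio of
#' abundance-weighted sums over the panel: fractions divide the feature
#' subset by its scope, per-antenna traits divide a sialic-acid or
#' galactose count weighted sum by the antenna-weighted sum, per-galactose
#' traits weight by galactoses, and group ratios divide two disjoint
#' scopes (e.g. high-mannose over hybrid). A sample whose denominator mass
#' is exactly zero gets a missing value for that trait.
#'
#' @param ab numeric matrix of relative abundances, samples x compositions;
#'   column names must match the panel's canonical labels and rows must sum
#'   to one (tolerance 1e-6).
#' @param defs trait definitions from [read_trait_panel()].
#' @param panel annotated panel the definitions were validated against.
#' @return numeric matrix, samples x traits.
#' @export
compute_traits <- function(ab, defs, panel) {
  labels <- panel$composition$label
  if (is.null(colnames(ab)) || !identical(sort(colnames(ab)), sort(labels))) {
    stop("abundance columns do not match the ", length(labels),
         " panel compositions")
  }
  ab <- ab[, labels, drop = FALSE]
  rs <- rowSums(ab)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("abundance rows are not normalized to one (worst deviation ",
         format(max(abs(rs - 1))), "); run total_area_normalize() first")
  }
  w <- trait_weights(defs, panel)
  num <- ab %*% w$num
  den <- ab %*% w$den
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Z-scale a trait matrix
#'
#' Centers and scales each trait to mean 0, SD 1 (n - 1 denominator),
#' excluding missing values; missing stays missing. Z-scaling is applied
#' per cohort so that per-SD effect estimates are comparable across cohorts
#' before meta-analysis.
#'
#' @param traits samples x traits matrix.
#' @return matrix of the same shape.
#' @export
zscale <- function(traits) {
  for (j in seq_len(ncol(traits))) {
    v <- traits[, j]
    ok <- !is.na(v)
    if (sum(ok) < 2L) {
      stop("trait ", colnames(traits)[j], ": fewer than 2 non-missing values")
    }
    s <- stats::sd(v[ok])
    if (!is.finite(s) || s < 1e-12) {
      stop("trait ", colnames(traits)[j], " has zero variance; cannot Z-scale")
    }
    traits[, j] <- (v - mean(v[ok])) / s
  }
  traits
}

#' Write / read a trait matrix as TSV
#'
#' Values round-trip losslessly (17 significant digits). The first column
#' holds the sample identifier.
#'
#' @param traits samples x traits matrix with row names.
#' @param path output path.
#' @param header_lines optional `#`-prefixed header comment lines.
#' @export
write_trait_tsv <- function(traits, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines(paste(c("sample_id", colnames(traits)), collapse = "\t"), con)
  body <- apply(traits, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rownames(traits), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_trait_tsv
#' @export
read_trait_tsv <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}
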