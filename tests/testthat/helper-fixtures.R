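# Shared fixtures: the packaged panel/trait spec loaded once, an
# independent brute-force trait oracle, and small builders used across
# test files.

panel_fx <- read_glycan_panel(tpng_panel_file())
defs_fx <- read_trait_panel(panel = panel_fx)

# Brute-force trait oracle: explicit double loop over compositions,
# independent of the matrix path in compute_traits().
oracle_traits <- function(ab, defs, panel) {
  an <- panel$annotation
  comp <- panel$composition
  out <- matrix(NA_real_, nrow(ab), nrow(defs),
                dimnames = list(rownames(ab), defs$name))
  for (s in seq_len(nrow(ab))) {
    for (d in seq_len(nrow(defs))) {
      num <- 0; den <- 0
      for (j in seq_len(nrow(comp))) {
        lab <- comp$label[j]
        in_scope <- selector_mask(defs$scope[d], panel)[j]
        w <- defs$weighting[d]
        if (w == "fraction") {
          if (in_scope) {
            den <- den + ab[s, lab]
            if (selector_mask(defs$feature[d], panel)[j]) {
              num <- num + ab[s, lab]
            }
          }
        } else if (w == "ratio") {
          if (in_scope) den <- den + ab[s, lab]
          if (selector_mask(defs$feature[d], panel)[j]) {
            num <- num + ab[s, lab]
          }
        } else {
          cnt <- switch(defs$feature[d], E = comp$E[j], L = comp$L[j],
                        S = comp$L[j] + comp$E[j], G = an$galactoses[j])
          unit <- if (w == "per-antenna") an$antennarity[j] else
            an$galactoses[j]
          if (in_scope) {
            num <- num + cnt * ab[s, lab]
            den <- den + unit * ab[s, lab]
          }
        }
      }
      out[s, d] <- if (den == 0) NA_real_ else num / den
    }
  }
  out
}

# A normalized abundance matrix with mass placed on named compositions.
abundance_fixture <- function(weights) {
  ab <- matrix(0, length(weights), nrow(panel_fx$composition),
               dimnames = list(names(weights) %||% paste0("s", seq_along(weights)),
                               panel_fx$composition$label))
  for (i in seq_along(weights)) {
    w <- weights[[i]]
    ab[i, names(w)] <- w
  }
  ab / rowSums(ab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_abundance <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(n * nrow(panel_fx$composition)), n)
  colnames(m) <- panel_fx$composition$label
  rownames(m) <- paste0("r", seq_len(n))
  m / rowSums(m)
}
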