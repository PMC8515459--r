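#' Parse glycan composition strings
#'
#' Parses mass-spectral N-glycan composition labels written in the
#' `H<n>N<n>F<n>L<n>E<n>` grammar: counts of hexose (H), N-acetylhexosamine
#' (N), fucose (F), alpha2,3-linked sialic acid (L) and alpha2,6-linked
#' sialic acid (E). H and N are mandatory; F, L and E default to zero;
#' monosaccharide codes may appear in any order but at most once. Total
#' sialylation S = L + E is always derived, never stored.
#'
#' @param text character vector of composition labels, e.g. `"H5N4F1E1"`.
#' @return a data.frame with one row per input and integer columns `H`, `N`,
#'   `F`, `L`, `E` plus the canonical `label` (order H, N, F, L, E, zero
#'   terms omitted). Parsing then printing the canonical label is idempotent.
#' @examples
#' parse_composition(c("H5N2", "H5N4F1E1", "E1H5N4F1"))
#' @export
parse_composition <- function(text) {
  stopifnot(is.character(text), length(text) >= 1L)
  out <- matrix(0L, nrow = length(text), ncol = 5L,
                dimnames = list(NULL, c("H", "N", "F", "L", "E")))
  for (i in seq_along(text)) {
    s <- text[[i]]
    if (is.na(s) || !nzchar(s)) {
      stop("empty composition string at position ", i)
    }
    toks <- regmatches(s, gregexpr("[A-Za-z][0-9]*", s))[[1]]
    if (!nzchar(gsub("[A-Za-z0-9]", "", s)) && paste(toks, collapse = "") != s) {
      stop("malformed composition '", s, "'")
    }
    if (paste(toks, collapse = "") != s) {
      bad <- substr(gsub("[A-Za-z][0-9]+", "", s), 1L, 8L)
      stop("malformed composition '", s, "': unparseable near '", bad, "'")
    }
    seen <- character(0)
    for (tok in toks) {
      code <- substr(tok, 1L, 1L)
      num <- substr(tok, 2L, nchar(tok))
      if (!code %in% c("H", "N", "F", "L", "E")) {
        stop("malformed composition '", s, "': unknown monosaccharide token '",
             tok, "'")
      }
      if (!nzchar(num)) {
        stop("malformed composition '", s, "': token '", tok,
             "' is missing its count")
      }
      if (code %in% seen) {
        stop("malformed composition '", s, "': duplicate monosaccharide code '",
             code, "'")
      }
      seen <- c(seen, code)
      out[i, code] <- as.integer(num)
    }
    if (!"H" %in% seen || !"N" %in% seen) {
      stop("malformed composition '", s, "': H and N counts are mandatory")
    }
    if (out[i, "N"] < 2L) {
      stop("composition '", s, "': N = ", out[i, "N"],
           " < 2; plasma N-glycans keep the chitobiose core (N >= 2)")
    }
  }
  comp <- as.data.frame(out)
  comp$label <- composition_label(comp)
  comp
}

#' Canonical composition label
#'
#' @param comp data.frame with columns `H`, `N`, `F`, `L`, `E`.
#' @return character vector of canonical labels (H, N, F, L, E order, zero
#'   F/L/E terms omitted).
#' @export
composition_label <- function(comp) {
  lab <- paste0("H", comp$H, "N", comp$N)
  for (code in c("F", "L", "E")) {
    add <- comp[[code]] > 0L
    lab[add] <- paste0(lab[add], code, comp[[code]][add])
  }
  lab
}

#' Structurally classify glycan compositions
#'
#' Assigns each composition a glycan class (high-mannose, hybrid, complex),
#' and for complex glycans an antennarity (1-4) and a bisection flag, using a
#' deterministic rule table:
#' \itemize{
#'   \item high-mannose: N = 2 and 4 <= H <= 9 (Man4-Man9), never
#'     fucosylated or sialylated;
#'   \item hybrid: N = 3 and H >= 5;
#'   \item complex: any other composition with N >= 3 and H >= 3;
#'     antennarity = min(N - 2, 4), except that a composition with
#'     N = a + 3 (1 <= a <= 4) and H <= a + 3 is read as bisected with
#'     antennarity a (an extra HexNAc on the core mannose rather than an
#'     extra antenna), e.g. N5 with H <= 5 is bisected diantennary while
#'     N5 with H6 is triantennary.
#' }
#' Galactose counts follow [galactose_count()]. Compositions whose sialic
#' acid count L + E exceeds the available galactoses are rejected (loud
#' failure on transcription errors rather than silent clipping); the same
#' applies to sialylated or fucosylated N = 2 species. Core and antenna
#' fucose cannot be distinguished at composition level, so F >= 1 simply
#' sets the fucosylation flag.
#'
#' @param comp data.frame from [parse_composition()].
#' @param override_class optional character vector (NA = no override) forcing
#'   the class of individual compositions where curated structure assignments
#'   disagree with the rule table.
#' @param override_antennarity,override_bisected optional per-composition
#'   overrides (NA = no override).
#' @return data.frame with columns `label`, `glycan_class`, `antennarity`
#'   (0 for non-complex), `bisected`, `galactoses`, `fucosylated`,
#'   `sialylated`.
#' @examples
#' classify_composition(parse_composition(c("H5N2", "H5N4F1E1", "H5N5F1")))
#' @export
classify_composition <- function(comp, override_class = NULL,
                                 override_antennarity = NULL,
                                 override_bisected = NULL) {
  n <- nrow(comp)
  cls <- character(n)
  ant <- integer(n)
  bis <- logical(n)
  for (i in seq_len(n)) {
    H <- comp$H[i]; N <- comp$N[i]
    if (N == 2L) {
      if (H < 4L || H > 9L) {
        stop("unclassifiable composition ", comp$label[i],
             ": N = 2 but H = ", H, " outside the high-mannose range 4..9")
      }
      cls[i] <- "high-mannose"
    } else if (N == 3L && H >= 5L) {
      cls[i] <- "hybrid"
    } else {
      if (H < 3L) {
        stop("unclassifiable composition ", comp$label[i],
             ": complex-type glycans need the trimannosyl core (H >= 3), got H = ",
             H, ", N = ", N)
      }
      cls[i] <- "complex"
      a_bis <- N - 3L
      if (a_bis >= 1L && a_bis <= 4L && H <= a_bis + 3L) {
        bis[i] <- TRUE
        ant[i] <- a_bis
      } else {
        ant[i] <- min(N - 2L, 4L)
      }
    }
    if (!is.null(override_class) && !is.na(override_class[i])) {
      cls[i] <- match.arg(override_class[i],
                          c("high-mannose", "hybrid", "complex"))
      if (cls[i] != "complex") { ant[i] <- 0L; bis[i] <- FALSE }
    }
    if (cls[i] == "complex") {
      if (!is.null(override_antennarity) && !is.na(override_antennarity[i])) {
        ant[i] <- as.integer(override_antennarity[i])
      }
      if (!is.null(override_bisected) && !is.na(override_bisected[i])) {
        bis[i] <- as.logical(override_bisected[i])
      }
      if (ant[i] < 1L || ant[i] > 4L) {
        stop("composition ", comp$label[i], ": antennarity ", ant[i],
             " outside 1..4")
      }
    } else {
      ant[i] <- 0L
      bis[i] <- FALSE
    }
  }
  S <- comp$L + comp$E
  gal <- integer(n)
  for (i in seq_len(n)) {
    if (cls[i] == "high-mannose") {
      if (comp$F[i] > 0L || S[i] > 0L) {
        stop("unclassifiable composition ", comp$label[i],
             ": high-mannose glycans carry no fucose or sialic acid (F = ",
             comp$F[i], ", L = ", comp$L[i], ", E = ", comp$E[i], ")")
      }
      gal[i] <- 0L
    } else if (cls[i] == "hybrid") {
      if (S[i] > 1L) {
        stop("composition ", comp$label[i], ": hybrid glycans have a single ",
             "decorated arm but L + E = ", S[i])
      }
      gal[i] <- S[i]
    } else {
      g <- min(comp$H[i] - 3L, ant[i])
      if (S[i] > g) {
        stop("composition ", comp$label[i], ": sialic acids exceed galactoses (",
             "L + E = ", S[i], " > ", g, " with H = ", comp$H[i],
             ", antennarity = ", ant[i], ")")
      }
      gal[i] <- g
    }
  }
  data.frame(label = comp$label, glycan_class = cls, antennarity = ant,
             bisected = bis, galactoses = gal,
             fucosylated = comp$F >= 1L, sialylated = S >= 1L,
             stringsAsFactors = FALSE)
}

#' Galactoses available on a composition
#'
#' For complex glycans the number of antenna galactoses is `min(H - 3,
#' antennarity)` (three core hexoses are mannose), floored at `L + E`
#' because every sialic acid sits on a galactose; for hybrid glycans
#' (antennarity recorded as 0) the floor is what carries the single
#' decorated arm, so galactoses = L + E; high-mannose glycans have none.
#'
#' @param comp data.frame from [parse_composition()].
#' @param annot matching annotation from [classify_composition()].
#' @return integer vector of galactose counts.
#' @export
galactose_count <- function(comp, annot) {
  ifelse(annot$glycan_class == "high-mannose", 0L,
         pmax(pmin(comp$H - 3L, annot$antennarity), comp$L + comp$E))
}

#' Read a glycan panel specification
#'
#' Reads a TSV panel file with a `composition` column and optional
#' `override_class`, `override_antennarity`, `override_bisected` columns
#' that pin individual structure assignments where curated knowledge
#' disagrees with the rule table. Lines starting with `#` are comments.
#'
#' @param path path to the panel TSV.
#' @return a list with `composition` (parsed counts) and `annotation`
#'   (classification), both in file order.
#' @export
read_glycan_panel <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"composition" %in% names(tab)) {
    stop("panel file ", path, " lacks a 'composition' column")
  }
  if (anyDuplicated(tab$composition)) {
    dup <- tab$composition[duplicated(tab$composition)][1]
    stop("panel file ", path, " lists composition '", dup, "' more than once")
  }
  comp <- parse_composition(tab$composition)
  oc <- if ("override_class" %in% names(tab)) as.character(tab$override_class)
  oa <- if ("override_antennarity" %in% names(tab)) tab$override_antennarity
  ob <- if ("override_bisected" %in% names(tab)) tab$override_bisected
  annot <- classify_composition(comp, override_class = oc,
                                override_antennarity = oa,
                                override_bisected = ob)
  list(composition = comp, annotation = annot)
}

#' Path to the packaged synthetic glycan panel
#'
#' The packaged panel is a constructed stand-in for a 68-composition total
#' plasma N-glycome panel (the original study's curated panel is not
#' publicly available): 68 compositions spanning high-mannose, hybrid and
#' complex mono- to tetra-antennary species with fucosylation, bisection
#' and linkage-differentiated sialylation.
#'
#' @return file path of the packaged panel TSV.
#' @export
tpng_panel_file <- function() {
  system.file("extdata", "glycan_panel_synthetic.tsv", package = "tpng",
              mustWork = TRUE)
}

#' Path to the packaged synthetic derived-trait specification
#'
#' 45 derived-trait definitions (fractions, per-antenna and per-galactose
#' ratios, and group ratios) constructed to cover the trait families of
#' total plasma N-glycome studies: complexity, fucosylation, bisection,
#' galactosylation and alpha2,3- vs alpha2,6-sialylation.
#'
#' @return file path of the packaged trait TSV.
#' @export
tpng_trait_file <- function() {
  system.file("extdata", "derived_traits_synthetic.tsv", package = "tpng",
              mustWork = TRUE)
}
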