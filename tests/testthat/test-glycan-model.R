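test_that("composition parsing reads counts, defaults and canonical order", {
  c1 <- parse_composition("H5N2")
  expect_equal(unlist(c1[, c("H", "N", "F", "L", "E")]),
               c(H = 5L, N = 2L, F = 0L, L = 0L, E = 0L))
  c2 <- parse_composition("H5N4F1E1")
  expect_equal(c2$E, 1L)
  expect_equal(c2$L, 0L)
  # order independence and canonical reprint
  expect_equal(parse_composition("E1H5N4F1")$label, "H5N4F1E1")
})

test_that("malformed compositions are rejected with the offending token", {
  expect_error(parse_composition("H5N4X1"), "X1")
  expect_error(parse_composition("H5N4H1"), "duplicate")
  expect_error(parse_composition("H5N1"), "N = 1")
  expect_error(parse_composition("N4F1"), "mandatory")
  expect_error(parse_composition("H5N"), "count")
})

test_that("parse and canonical print round-trip over the whole panel", {
  labels <- panel_fx$composition$label
  expect_identical(parse_composition(labels)$label, labels)
})

test_that("the rule table classifies the reference species", {
  an <- classify_composition(parse_composition(
    c("H5N2", "H5N4F1E1", "H5N5F1", "H6N5", "H6N3", "H3N3")))
  expect_equal(an$glycan_class,
               c("high-mannose", "complex", "complex", "complex", "hybrid",
                 "complex"))
  # H5N4F1E1: diantennary, digalactosylated, fucosylated, sialylated
  expect_equal(an$antennarity[2], 2L)
  expect_equal(an$galactoses[2], 2L)
  expect_true(an$fucosylated[2] && an$sialylated[2] && !an$bisected[2])
  # H5N5F1: bisected diantennary (N = antennarity + 3, H <= 5)
  expect_true(an$bisected[3])
  expect_equal(an$antennarity[3], 2L)
  expect_equal(an$galactoses[3], 2L)
  # H6N5: triantennary, not bisected (H = 6 exceeds the bisection bound)
  expect_false(an$bisected[4])
  expect_equal(an$antennarity[4], 3L)
  # monoantennary complex
  expect_equal(an$antennarity[6], 1L)
})

test_that("impossible compositions are rejected loudly", {
  expect_error(classify_composition(parse_composition("H4N2F1")),
               "high-mannose")
  expect_error(classify_composition(parse_composition("H3N2")), "4..9")
  # sialylation cap: more sialic acids than galactoses
  expect_error(classify_composition(parse_composition("H5N4E3")),
               "exceed galactoses")
  expect_error(classify_composition(parse_composition("H4N4E2")),
               "exceed galactoses")
  # hybrid with two decorated arms
  expect_error(classify_composition(parse_composition("H6N3E1L1")),
               "single")
})

test_that("classes partition the packaged panel with stable counts", {
  cls <- table(panel_fx$annotation$glycan_class)
  expect_equal(sum(cls), 68L)
  expect_equal(as.integer(cls[c("high-mannose", "hybrid", "complex")]),
               c(6L, 6L, 56L))
  # every composition has exactly one class
  expect_true(all(panel_fx$annotation$glycan_class %in%
                    c("high-mannose", "hybrid", "complex")))
})

test_that("adding sialic acid never lowers the sialylated flag or changes antennarity", {
  comp <- panel_fx$composition
  for (j in seq_len(nrow(comp))) {
    base <- classify_composition(comp[j, ])  # rule table, no overrides
    if (base$glycan_class != "complex") next
    for (code in c("E", "L")) {
      plus <- comp[j, ]
      plus[[code]] <- plus[[code]] + 1L
      if (plus$L + plus$E > min(plus$H - 3L, base$antennarity)) next
      plus$label <- composition_label(plus)
      an2 <- classify_composition(plus)
      expect_true(an2$sialylated)
      expect_equal(an2$antennarity, base$antennarity)
    }
  }
})

test_that("galactose counts follow min(H - 3, antennarity) with the hybrid floor", {
  ex <- parse_composition(c("H5N4", "H4N4", "H6N5", "H6N3E1", "H5N2"))
  # H4N4 pinned to A2 as in the packaged panel overrides
  an <- classify_composition(ex, override_class = c(NA, "complex", NA, NA, NA),
                             override_antennarity = c(NA, 2L, NA, NA, NA),
                             override_bisected = c(NA, FALSE, NA, NA, NA))
  expect_equal(galactose_count(ex, an), c(2L, 1L, 3L, 1L, 0L))
})

test_that("panel overrides pin the agalactosylated diantennary species", {
  an <- panel_fx$annotation
  g0 <- an[an$label %in% c("H3N4", "H3N4F1", "H4N4", "H4N4F1"), ]
  expect_true(all(g0$antennarity == 2L))
  expect_true(all(!g0$bisected))
  # without the override the rule table reads H3N4F1 as bisected A1
  free <- classify_composition(parse_composition("H3N4F1"))
  expect_true(free$bisected)
  expect_equal(free$antennarity, 1L)
})

test_that("duplicate panel rows are rejected", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("composition", "H5N4", "H5N4"), tmp)
  expect_error(read_glycan_panel(tmp), "more than once")
})
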