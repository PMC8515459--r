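write_trait_spec <- function(lines) {
  tmp <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("name\tscope\tfeature\tweighting", lines), tmp)
  tmp
}

test_that("the packaged spec defines 45 uniquely named, nonempty traits", {
  expect_equal(nrow(defs_fx), 45L)
  expect_false(anyDuplicated(defs_fx$name) > 0)
  for (i in seq_len(nrow(defs_fx))) {
    expect_true(any(selector_mask(defs_fx$scope[i], panel_fx)))
  }
})

test_that("invalid trait specs fail loudly", {
  # pentaantennary selector: unknown keyword (antennarity tops out at 4)
  bad1 <- write_trait_spec("X\tcomplex&A5\tF\tfraction")
  expect_error(read_trait_panel(bad1, panel_fx), "unknown selector keyword")
  # empty scope over the packaged panel
  bad2 <- write_trait_spec("X\thighman&F\tB\tfraction")
  expect_error(read_trait_panel(bad2, panel_fx), "no packaged composition")
  # duplicate trait name
  bad3 <- write_trait_spec(c("A2FS0B\tcomplex&A2&F&S0\tB\tfraction",
                             "A2FS0B\tcomplex&A2&F&S0\tB\tfraction"))
  expect_error(read_trait_panel(bad3, panel_fx), "duplicate")
  # unknown weighting
  bad4 <- write_trait_spec("X\tcomplex\tF\tgeometric")
  expect_error(read_trait_panel(bad4, panel_fx), "weighting")
})

test_that("hand-computed trait values match", {
  ab <- abundance_fixture(list(
    pure = c(H5N5F1 = 1),
    mixed = c(H5N4F1 = 0.6, H5N5F1 = 0.2, H5N2 = 0.2),
    ratio = c(H5N2 = 0.10, H5N3 = 0.05, H5N4E2 = 0.85)))
  tr <- compute_traits(ab, defs_fx, panel_fx)
  # numerator equals denominator: all fucosylated non-sialylated A2 mass
  # sits on the bisected species
  expect_equal(tr["pure", "A2FS0B"], 1.0)
  # 0.2 bisected of 0.8 total fucosylated non-sialylated A2
  expect_equal(tr["mixed", "A2FS0B"], 0.25)
  # high-mannose / hybrid = 0.10 / 0.05
  expect_equal(tr["ratio", "MHy"], 2.0)
  # empty denominator propagates missing: no A4 mass in "pure"
  expect_true(is.na(tr["pure", "A4E"]))
})

test_that("trait computation equals the brute-force oracle on random samples", {
  ab <- random_abundance(100, seed = 42)
  fast <- compute_traits(ab, defs_fx, panel_fx)
  slow <- oracle_traits(ab, defs_fx, panel_fx)
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("fraction traits stay in [0, 1] and complements sum to one", {
  ab <- random_abundance(50, seed = 7)
  tr <- compute_traits(ab, defs_fx, panel_fx)
  frac <- defs_fx$name[defs_fx$weighting %in%
                         c("fraction", "per-antenna", "per-galactose")]
  expect_true(all(tr[, frac] >= -1e-12 & tr[, frac] <= 1 + 1e-12,
                  na.rm = TRUE))
  # complementary pair over an identical scope
  comp_defs <- read_trait_panel(write_trait_spec(c(
    "FUC\tcomplex&A2\tF\tfraction",
    "NONFUC\tcomplex&A2\tF0\tfraction")), panel_fx)
  ctr <- compute_traits(ab, comp_defs, panel_fx)
  expect_equal(unname(rowSums(ctr)), rep(1, nrow(ab)), tolerance = 1e-12)
  # antennarity fractions within complex partition to one
  expect_equal(unname(rowSums(tr[, c("CA1", "CA2", "CA3", "CA4")])),
               rep(1, nrow(ab)), tolerance = 1e-12)
})

test_that("traits are invariant to per-sample intensity scaling", {
  set.seed(9)
  raw <- matrix(stats::rexp(20 * 68), 20)
  colnames(raw) <- panel_fx$composition$label
  rownames(raw) <- paste0("s", 1:20)
  scaled <- raw * stats::runif(20, 0.1, 50)
  t1 <- compute_traits(total_area_normalize(raw), defs_fx, panel_fx)
  t2 <- compute_traits(total_area_normalize(scaled), defs_fx, panel_fx)
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("Z-scaling centers, scales and preserves missingness", {
  m <- cbind(a = c(1, 2, 3), b = c(5, NA, 7))
  rownames(m) <- paste0("s", 1:3)
  z <- zscale(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_true(is.na(z[2, "b"]))
  expect_error(zscale(cbind(const = c(2, 2, 2))), "zero variance")
  # post-condition sweep on random data
  ab <- random_abundance(40, seed = 3)
  z2 <- zscale(compute_traits(ab, defs_fx, panel_fx))
  mu <- colMeans(z2, na.rm = TRUE)
  sds <- apply(z2, 2, stats::sd, na.rm = TRUE)
  expect_true(all(abs(mu) < 1e-12))
  expect_true(all(abs(sds - 1) < 1e-12))
})

test_that("trait matrices round-trip through TSV losslessly", {
  tr <- compute_traits(random_abundance(5, seed = 1), defs_fx, panel_fx)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_trait_tsv(tr, tmp, header_lines = "fixture")
  expect_identical(read_trait_tsv(tmp), tr)
})
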