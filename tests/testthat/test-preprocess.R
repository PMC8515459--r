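test_that("total-area normalization divides rows by their sums", {
  raw <- rbind(a = c(2, 2, 4), b = c(0.25, 0.25, 0.5))
  colnames(raw) <- c("x", "y", "z")
  norm <- total_area_normalize(raw)
  expect_equal(unname(norm["a", ]), c(0.25, 0.25, 0.5))
  # already-normalized rows are unchanged and the op is idempotent
  expect_equal(norm["b", ], raw["b", ])
  expect_equal(total_area_normalize(norm), norm, ignore_attr = TRUE)
  # random sweep
  set.seed(1)
  m <- matrix(stats::rexp(300), 20)
  expect_equal(rowSums(total_area_normalize(m)), rep(1, 20),
               tolerance = 1e-12)
})

test_that("all-zero spectra are dropped and reported", {
  raw <- rbind(ok = c(1, 2), dead = c(0, 0))
  expect_warning(norm <- total_area_normalize(raw), "all-zero")
  expect_equal(rownames(norm), "ok")
  expect_equal(attr(norm, "exclusions")$sample_id, "dead")
})

test_that("QC filtering excludes low-intensity spectra and reports them", {
  raw <- rbind(a = c(5, 5), b = c(6, 6), c = c(0.5, 0.5))
  expect_equal(nrow(qc_filter(raw, min_total_intensity = 0)$raw), 3L)
  res <- qc_filter(raw, min_total_intensity = 2)
  expect_equal(res$exclusions$sample_id, "c")
  expect_equal(res$exclusions$value, 1)
  expect_error(qc_filter(raw, min_total_intensity = 1e6), "every sample")
})

test_that("planted low-intensity fraction is recovered by the QC filter", {
  cfg <- default_sim_config()
  cfg$low_intensity_rate <- 0.02
  gly <- simulate_glycome(panel_fx, 1000, cfg, seed = 21)
  res <- qc_filter(gly$raw)
  frac <- nrow(res$exclusions) / 1000
  expect_equal(frac, 0.02, tolerance = 1e-9)  # exact planted count
})

test_that("replicate RSD matches hand calculations", {
  tr <- rbind(r1 = c(t1 = 9, t2 = 4), r2 = c(t1 = 11, t2 = 4))
  res <- replicate_rsd(tr, c("pool", "pool"))
  expect_equal(unname(res$per_trait["t1"]), 100 * sqrt(2) / 10,
               tolerance = 1e-12)
  expect_equal(unname(res$per_trait["t2"]), 0)
  expect_error(replicate_rsd(tr, c("a", "b")), "replicate group")
})

test_that("simulated technical CV is recovered as replicate RSD", {
  cfg <- default_sim_config()
  cfg$plate_sd <- 0  # isolate technical noise from plate shifts
  gly <- simulate_glycome(panel_fx, 400, cfg, seed = 31)
  ab <- total_area_normalize(gly$raw)
  res <- replicate_rsd(ab, gly$info$replicate_group)
  # direct composition RSDs track the 5% per-composition technical CV
  expect_equal(res$mean_rsd, 5, tolerance = 0.15)
  # zero technical noise => zero RSD for every derived trait
  cfg$technical_cv <- 0
  gly0 <- simulate_glycome(panel_fx, 200, cfg, seed = 32)
  tr0 <- compute_traits(total_area_normalize(gly0$raw), defs_fx, panel_fx)
  res0 <- replicate_rsd(tr0, gly0$info$replicate_group)
  expect_true(all(res0$per_trait < 1e-9))
})

test_that("batch correction is calm under the null and fixes planted shifts", {
  set.seed(5)
  n <- 160; p <- 20
  x <- matrix(rnorm(n * p, mean = rep(1:p, each = n)), n)
  colnames(x) <- paste0("f", 1:p)
  batch <- rep(c("b1", "b2"), each = n / 2)
  # null: same distribution in both batches, output stays close to input
  out <- batch_correct(x, batch)
  expect_equal(colMeans(out), colMeans(x), tolerance = 1e-3)
  expect_true(max(abs(out - x)) < 0.5)  # well under the unit feature SD
  expect_true(all(diag(stats::cor(out, x)) > 0.98))
  # without shrinkage the location-scale reconstruction preserves each
  # feature's grand mean essentially exactly
  out_ns <- batch_correct(x, batch, eb = FALSE)
  expect_equal(colMeans(out_ns), colMeans(x), tolerance = 1e-9)
  # planted constant location shift is removed almost entirely
  delta <- 1
  x2 <- x
  x2[batch == "b2", ] <- x2[batch == "b2", ] + delta
  out2 <- batch_correct(x2, batch)
  gap <- function(m) abs(colMeans(m[batch == "b1", ]) -
                           colMeans(m[batch == "b2", ]))
  expect_lt(mean(gap(out2)), 0.1 * delta)
  expect_true(all(gap(out2) < gap(x2)))
  expect_true(all(gap(batch_correct(x2, batch, eb = FALSE)) < 1e-9))
  # relabeling batches changes nothing
  relab <- c(b1 = "plateB", b2 = "plateA")[batch]
  expect_equal(batch_correct(x2, relab), out2)
})

test_that("batch correction matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  set.seed(11)
  n <- 90; p <- 25
  x <- matrix(rnorm(n * p, mean = 2, sd = 1.2), n)
  colnames(x) <- paste0("f", 1:p)
  batch <- rep(c("a", "b", "c"), each = 30)
  x[batch == "b", ] <- x[batch == "b", ] + 0.8
  x[batch == "c", ] <- x[batch == "c", ] * 1.3
  mine <- batch_correct(x, batch)
  ref <- t(suppressMessages(sva::ComBat(t(x), batch = batch)))
  expect_equal(mine, ref, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("singleton batches are refused with advice", {
  x <- matrix(rnorm(30), 10, 3)
  expect_error(batch_correct(x, c(rep("a", 9), "b")), "merge")
})
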