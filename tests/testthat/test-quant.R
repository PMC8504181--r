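test_that("control-median normalization is exact arithmetic", {
  expect_equal(normalize_to_control_median(c(2, 4, 6), c(2, 4, 6)),
               c(0.5, 1, 1.5))
  expect_equal(normalize_to_control_median(c(1, 2), c(2, 4, 6)), c(0.25, 0.5))
  expect_error(normalize_to_control_median(1, numeric(0)), "empty")
  expect_error(normalize_to_control_median(1, c(0, 0)), "positive")
})

test_that("per-replicate normalization keeps the pooled control median at 1", {
  cells <- data.frame(
    cell_id = paste0("c", 1:12),
    replicate = rep(1:2, each = 6),
    condition = rep(c("basal", "basal", "basal", "Bic", "Bic", "Bic"), 2),
    mean_intensity = c(2, 4, 6, 1, 2, 3,    # replicate 1
                       10, 20, 30, 5, 10, 15))  # replicate 2, scaled 5x
  out <- normalize_cells(cells, "basal")
  # within each replicate the control median is exactly 1
  for (r in 1:2) {
    expect_equal(median(out$normalized_intensity[out$replicate == r &
                                                   out$condition == "basal"]), 1)
  }
  # balanced replicates: pooled control median is still 1
  expect_equal(median(out$normalized_intensity[out$condition == "basal"]), 1)
  # the 5x between-replicate scale is absorbed
  expect_equal(out$normalized_intensity[1:6], out$normalized_intensity[7:12])
})

test_that("marker normalization is an elementwise ratio with exclusions", {
  expect_equal(normalize_to_marker(6, 3), 2)
  expect_equal(normalize_to_marker(0, 3), 0)
  v <- c(2, 4, 8)
  m <- c(1, 2, 4)
  expect_equal(normalize_to_marker(v, m * 2), normalize_to_marker(v, m) / 2)
  expect_warning(out <- normalize_to_marker(c(1, 2), c(1, 0)), "excluded")
  expect_true(is.na(out[2]))
})

test_that("Western ratios normalize to loading control and basal sample", {
  expect_equal(ratio_to_loading_control(10, 2, 5), 1)  # the basal sample itself
  expect_equal(ratio_to_loading_control(5, 2, 5), 0.5)
  expect_equal(ratio_to_loading_control(10, 4, 5),
               ratio_to_loading_control(5, 2, 5))  # ratio invariance
  expect_error(ratio_to_loading_control(1, 0, 1), "positive")
})

test_that("qPCR relative expression matches the worked examples", {
  rec <- function(sample, gene, role, Ct, E = 2) {
    data.frame(sample = sample, gene = gene, role = role, Ct = Ct,
               efficiency = E)
  }
  # all delta Ct zero -> 1
  r <- rbind(rec("cal", "tgt", "TARGET", 20), rec("s1", "tgt", "TARGET", 20),
             rec("cal", "hk", "HOUSEKEEPING", 18), rec("s1", "hk", "HOUSEKEEPING", 18))
  out <- qpcr_relative_expression(r, "cal")
  expect_equal(out$relative_expression, c(1, 1))

  # E = 2, target dCt = 2, housekeeping dCt = 0 -> 4
  r <- rbind(rec("cal", "tgt", "TARGET", 22), rec("s1", "tgt", "TARGET", 20),
             rec("cal", "hk1", "HOUSEKEEPING", 18), rec("s1", "hk1", "HOUSEKEEPING", 18),
             rec("cal", "hk2", "HOUSEKEEPING", 19), rec("s1", "hk2", "HOUSEKEEPING", 19))
  out <- qpcr_relative_expression(r, "cal")
  expect_equal(out$relative_expression[out$sample == "s1"], 4)
  expect_equal(out$relative_expression[out$sample == "cal"], 1)

  # target dCt = 2, housekeeping dCt {1, 3}: 4 / geomean(2, 8) = 1
  r <- rbind(rec("cal", "tgt", "TARGET", 22), rec("s1", "tgt", "TARGET", 20),
             rec("cal", "hk1", "HOUSEKEEPING", 19), rec("s1", "hk1", "HOUSEKEEPING", 18),
             rec("cal", "hk2", "HOUSEKEEPING", 21), rec("s1", "hk2", "HOUSEKEEPING", 18))
  out <- qpcr_relative_expression(r, "cal")
  expect_equal(out$relative_expression[out$sample == "s1"], 1)

  # technical triplicates collapse by mean Ct
  r <- rbind(rec("cal", "tgt", "TARGET", c(21, 22, 23)),
             rec("s1", "tgt", "TARGET", 20),
             rec("cal", "hk", "HOUSEKEEPING", 18),
             rec("s1", "hk", "HOUSEKEEPING", 18))
  out <- qpcr_relative_expression(r, "cal")
  expect_equal(out$relative_expression[out$sample == "s1"], 4)

  # missing housekeeping measurement errors
  r <- rbind(rec("cal", "tgt", "TARGET", 20), rec("s1", "tgt", "TARGET", 20),
             rec("cal", "hk", "HOUSEKEEPING", 18))
  expect_error(qpcr_relative_expression(r, "cal"), "housekeeping")

  # direction flag flips the exponent
  r <- rbind(rec("cal", "tgt", "TARGET", 22), rec("s1", "tgt", "TARGET", 20),
             rec("cal", "hk", "HOUSEKEEPING", 18), rec("s1", "hk", "HOUSEKEEPING", 18))
  out <- qpcr_relative_expression(r, "cal", delta_ct = "sample_minus_calibrator")
  expect_equal(out$relative_expression[out$sample == "s1"], 1 / 4)
})

test_that("Mann-Whitney U matches enumeration and satisfies symmetry", {
  # U = 0, exact two-sided p = 2/20 = 0.1
  t <- mwu_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t$U, 0)
  expect_equal(t$p, 0.1)
  expect_equal(t$method, "exact")
  expect_equal(t$p, mwu_enum_oracle(c(1, 2, 3), c(4, 5, 6)))

  # identical groups -> p = 1 (all ties: normal branch)
  t2 <- mwu_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t2$p, 1)

  # symmetry: swapping groups maps U to n1*n2 - U and keeps p
  set.seed(8)
  for (k in 1:10) {
    a <- rnorm(sample(2:7, 1))
    b <- rnorm(sample(2:7, 1))
    f <- mwu_test(a, b)
    r <- mwu_test(b, a)
    expect_equal(f$U, length(a) * length(b) - r$U)
    expect_equal(f$p, r$p, tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation branches agree for 8 vs 8", {
  set.seed(15)
  for (k in 1:50) {
    a <- rnorm(8)
    b <- rnorm(8, mean = runif(1, -1, 1))
    exact <- mwu_test(a, b)$p
    approx <- mwu_test(a, b, exact_max = 0L)$p
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("normal approximation with ties tracks the standard test", {
  set.seed(23)
  for (k in 1:10) {
    a <- sample(1:6, 12, replace = TRUE)
    b <- sample(1:8, 15, replace = TRUE)
    mine <- mwu_test(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(mine$method, "normal")
    expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
    expect_equal(mine$U, unname(ref$statistic))
  }
})

test_that("Bonferroni correction multiplies by planned comparisons and caps", {
  groups <- list(basal = c(1, 2, 3, 4), TTX = c(2, 3, 4, 5),
                 Bic = c(8, 9, 10, 11))
  res <- mwu_bonferroni(groups, c("basal:Bic", "TTX:Bic", "basal:TTX"))
  expect_equal(res$bonferroni_p, pmin(1, 3 * res$p))
  expect_true(all(res$bonferroni_p >= res$p))
  expect_true(all(res$U <= res$n_a * res$n_b))
  # k * p rule on a known raw p: {1,2,3} vs {4,5,6} has exact p 0.1
  g2 <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(0, 0.5, 1))
  r2 <- mwu_bonferroni(g2, list(c("a", "b"), c("a", "c"), c("b", "c")))
  expect_equal(r2$bonferroni_p[1], 0.3)
  # capping at 1
  g3 <- list(x = c(1, 2, 3), y = c(1.5, 2.5, 3.5))
  r3 <- mwu_bonferroni(g3, rep(list(c("x", "y")), 5))
  expect_equal(r3$bonferroni_p, rep(1, 5))
  expect_error(mwu_bonferroni(groups, list(c("basal", "missing"))), "groups")
})
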