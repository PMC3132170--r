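# Nested model fits, F comparisons, rank-sum, strata, resampling.

test_that("hand-computed nested F: 4-point example", {
  tab <- data.table(
    i = 1:4, j = 5:8, chrom_i = "chr1", chrom_j = "chr1",
    GD = exp(c(0, 0, 1, 1)), inter = FALSE,
    NR = 1, SDR = 0, NRCSD = exp(1:4),
    BP = c(FALSE, FALSE, TRUE, TRUE)
  )
  tab[, log_RC := log(NRCSD)]; tab[, log_GD := log(GD)]
  # y = 1,2,3,4 against binary x (here BP): intercept-only vs intercept + BP
  rows <- 1:4
  small <- fit_model(model_spec("null", character(0)), tab, rows = rows)
  big <- fit_model(model_spec("bp", "BP"), tab, rows = rows)
  cmp <- compare_nested_models(small, big)
  expect_equal(cmp$f, 8)
  expect_equal(c(cmp$df1, cmp$df2), c(1L, 2L))
  expect_equal(cmp$p, 0.10557, tolerance = 1e-4)
  # independent oracle: stats::anova on the same lm objects
  an <- anova(small$fit, big$fit)
  expect_equal(cmp$f, an$F[2])
  expect_equal(cmp$p, an$`Pr(>F)`[2])
})

test_that("noiseless data generated from M1 is recovered to machine precision", {
  g <- build_locus_grid(data.table(chrom = "chr1", size = 40e6), 1e6)
  ep <- enumerate_locus_pairs(g)[i < j]
  flags <- ep[seq(1, .N, by = 7)]
  tab <- assemble_pair_table(pair_counts_from_triples(
    data.table(i = 1L, j = 2L, count = 0), g), g, flags)
  tab[, log_RC := 2.5 - 0.9 * log_GD + 0.4 * as.numeric(BP)]
  f <- suppressWarnings(fit_model(ancova_models()$M1, tab))  # perfect-fit warning
  expect_equal(unname(coef(f$fit)), c(2.5, -0.9, 0.4), tolerance = 1e-10)
})

test_that("degenerate and ill-posed fits are rejected", {
  tab <- sim_pair_table(20, 5, contact_config(seed = 2), 2)
  noflag <- copy(tab)[, BP := FALSE]
  expect_error(fit_model(ancova_models()$M1, noflag), "degenerate BP")
  f0 <- fit_model(ancova_models()$M0, tab)
  f1 <- fit_model(ancova_models()$M1, tab)
  expect_error(compare_nested_models(f1, f0), "not nested|not a subset")
  expect_error(compare_nested_models(f0, f0), "adds no term")
  f1b <- fit_model(ancova_models()$M1, tab, rows = f1$rows[-1])
  expect_error(compare_nested_models(fit_model(ancova_models()$M0, tab), f1b),
               "different rows")
})

test_that("F equals squared t for a single added coefficient", {
  tab <- sim_pair_table(40, 20, contact_config(seed = 6), 6)
  cmp <- compare_models(tab, ancova_models()$M0, ancova_models()$M1)
  tstat <- cmp$big$coefficients["BP", "t value"]
  expect_equal(cmp$test$f, tstat^2, tolerance = 1e-8)
})

test_that("nested F p-values are uniform under the null", {
  set.seed(31)
  ps <- replicate(300, {
    tab <- data.table(
      GD = exp(runif(150, 0, 3)), inter = FALSE,
      BP = sample(c(TRUE, FALSE), 150, replace = TRUE, prob = c(0.2, 0.8))
    )
    tab[, log_GD := log(GD)]
    tab[, log_RC := 1 - 0.5 * log_GD + rnorm(150, 0, 0.5)]
    rows <- seq_len(150)
    small <- fit_model(ancova_models()$M0, tab, rows = rows)
    big <- fit_model(ancova_models()$M1, tab, rows = rows)
    compare_nested_models(small, big)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("rank-sum test matches exact enumeration and handles ties", {
  out <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$p, 0.1)  # 2/20 arrangements as extreme, two-sided
  tied <- suppressWarnings(ranksum_test(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(tied$p, 1)
  expect_error(ranksum_test(numeric(0), 1), "non-empty")
  # power grows with shift
  set.seed(12)
  pow <- vapply(c(0.5, 1.5, 3), function(sh) {
    mean(replicate(60, {
      a <- rnorm(25); b <- rnorm(25) + sh
      ranksum_test(b, a)$p < 0.05
    }))
  }, numeric(1))
  expect_true(all(diff(pow) >= 0))
})

test_that("strata: distance, gene and DNase classes follow the thresholds", {
  tab <- data.table(
    i = c(1L, 1L, 1L, 2L, 3L), j = c(2L, 3L, 9L, 2L, 5L),
    GD = c(1, 2, NA, 0, 4), inter = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    BP = FALSE, NRCSD = 1,
    Gcov = c(0, 0.05, 0.2, 0.3, 0.9),
    d_i = c(1, 1, 5, 5, 5), d_j = c(1, 5, 5, 1, 5)
  )
  sg <- assign_strata(tab, stratum_scheme(distance = FALSE, gene = TRUE))
  expect_equal(sg, c("G0", "G1", "G2", "G3", "G3"))
  sd_ <- assign_strata(tab, stratum_scheme(distance = FALSE, dnase = TRUE))
  expect_equal(sd_, c("poor-poor", "poor-rich", "rich-rich", "poor-rich", "rich-rich"))
  di <- assign_strata(tab, stratum_scheme(n_distance = 2))
  expect_equal(di[3], "inter")
  expect_true(is.na(di[4]))  # self-pair unclassifiable by log distance
  expect_equal(di[1], "D1")
  expect_equal(di[5], "D2")
})

test_that("resampling: constant data gives p = 1, inflated flags give 1/(B+1)", {
  tab <- sim_pair_table(30, 10, contact_config(seed = 4), 4)
  const <- copy(tab)[, NRCSD := 7]
  r1 <- stratified_resampling_test(const, stratum_scheme(), B = 99, seed = 1)
  expect_equal(r1$p, 1)
  expect_equal(r1$observed, 7)
  boost <- copy(tab)[BP == TRUE, NRCSD := NRCSD + 1e7]
  r2 <- stratified_resampling_test(boost, stratum_scheme(), B = 99, seed = 1)
  expect_equal(r2$p, 1 / 100)
  # deterministic under the seed; invariant to order-preserving relabeling
  r3 <- stratified_resampling_test(boost, stratum_scheme(), B = 99, seed = 1)
  expect_identical(r2$null, r3$null)
})

test_that("resampling rejects when a stratum lacks unflagged pairs", {
  tab <- data.table(
    i = 1:6, j = 3:8, GD = c(1, 1, 1, 8, 8, 8), inter = FALSE,
    BP = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), NRCSD = 1:6
  )
  expect_error(stratified_resampling_test(tab, stratum_scheme(n_distance = 2), B = 10, seed = 1),
               "stratum")
})
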