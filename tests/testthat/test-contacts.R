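# Contact-count, covariate-track and SD-bias simulators.

test_that("noiseless counts follow the closed-form mean", {
  g <- build_locus_grid(data.table(chrom = "chr1", size = 10e6), 1e6)
  tr <- simulate_contact_counts(g, NULL, contact_config(sigma = 0, seed = 1))
  expect_equal(tr[i == 1 & j == 2, count], round(exp(6.0)))  # 403 at GD = 1
  # doubling GD multiplies the mean by 2^a
  r <- tr[i == 1 & j == 5, count] / tr[i == 1 & j == 3, count]  # GD 4 vs 2
  expect_equal(r, 2^-0.8, tolerance = 0.02)
  # breakpoint effect enters as b + c log(GD)
  tr_bp <- simulate_contact_counts(g, data.table(i = 1L, j = 2L),
                                   contact_config(sigma = 0, seed = 1))
  expect_equal(tr_bp[i == 1 & j == 2, count], round(exp(6.0 + 0.728)))
})

test_that("counts are non-negative integers and seed-deterministic", {
  g <- build_locus_grid(data.table(chrom = "chr1", size = 20e6, stringsAsFactors = FALSE), 1e6)
  cfg <- contact_config(sigma = 0.5, seed = 42)
  t1 <- simulate_contact_counts(g, NULL, cfg)
  t2 <- simulate_contact_counts(g, NULL, cfg)
  expect_identical(t1$count, t2$count)
  expect_true(all(t1$count == floor(t1$count) & t1$count >= 0))
  t3 <- simulate_contact_counts(g, NULL, contact_config(sigma = 0.5, seed = 43))
  expect_false(identical(t1$count, t3$count))
})

test_that("explicit intra pair at GD <= 0 is rejected", {
  g <- build_locus_grid(data.table(chrom = "chr1", size = 5e6), 1e6)
  expect_error(simulate_contact_counts(g, NULL, contact_config(seed = 1),
                                       pairs = data.table(i = 2L, j = 2L)),
               "GD <= 0")
})

test_that("inter-chromosomal counts have the configured low mean", {
  g <- build_locus_grid(data.table(chrom = c("chr1", "chr2"), size = c(30e6, 30e6)), 1e6)
  tr <- simulate_contact_counts(g, NULL, contact_config(seed = 5))
  exp_tab <- attr(tr, "expected")
  inter_keys <- exp_tab[inter == TRUE, paste(i, j)]
  inter_counts <- tr[paste(i, j) %in% inter_keys, count]
  # sparse triples drop zeros; reconstruct the mean over all inter pairs
  m <- sum(inter_counts) / length(inter_keys)
  expect_gt(m, 4); expect_lt(m, 6)
})

test_that("with sigma = 0 the regression over non-flagged pairs recovers the slope", {
  g <- build_locus_grid(data.table(chrom = "chr1", size = 142e6), 1e6)  # 10,011 pairs
  tr <- simulate_contact_counts(g, NULL, contact_config(sigma = 0, seed = 2))
  e <- attr(tr, "expected")
  dat <- merge(e[!inter & GD >= 1], tr, by = c("i", "j"))
  fit <- lm(log(count) ~ log(GD), data = dat)
  expect_lt(abs(unname(coef(fit)[2]) - (-0.8)), 0.01)
})

test_that("covariate tracks: null configuration is exchangeable, enrichment raises means", {
  g <- build_locus_grid(data.table(chrom = "chr1", size = 1000e6), 1e6)
  bp <- 1:500
  null_cfg <- track_config(sd_enrich = 1, gene_enrich = 1, dnase_enrich = 1, seed = 8)
  tr <- simulate_covariate_tracks(g, bp, null_cfg)
  for (col in c("sd_frac", "gene_density", "dnase")) {
    p <- suppressWarnings(ks.test(tr[[col]][bp], tr[[col]][-bp])$p.value)
    expect_gt(p, 0.01)
  }
  rich_cfg <- track_config(sd_enrich = 3, gene_enrich = 2, dnase_enrich = 2, seed = 8)
  tr2 <- simulate_covariate_tracks(g, bp, rich_cfg)
  expect_gt(mean(tr2$sd_frac[bp]), mean(tr2$sd_frac[-bp]))
  expect_gt(mean(tr2$gene_density[bp]), mean(tr2$gene_density[-bp]))
  expect_gt(mean(tr2$dnase[bp]), mean(tr2$dnase[-bp]))
  expect_true(all(tr2$sd_frac >= 0 & tr2$sd_frac <= 1))
  expect_true(all(tr2$gene_density >= 0 & tr2$gene_density <= 1))
  expect_true(all(tr2$dnase >= 0))
  # determinism
  expect_identical(tr$sd_frac, simulate_covariate_tracks(g, bp, null_cfg)$sd_frac)
})

test_that("gap windows round-trip into locus filtering", {
  fx <- small_fixture(n_gap_windows = 2)
  gaps <- which(fx$tracks$gap_frac > 0.5)
  expect_length(gaps, 2L)
  g2 <- build_locus_grid(attr(fx$grid, "chrom_sizes"), 1e6)
  g2$gap_frac <- fx$tracks$gap_frac
  kept <- filter_loci(g2)
  expect_false(any(gaps %in% kept$idx))
})

test_that("SD bias: identity at rate 0, conservation, bounds", {
  g <- build_locus_grid(data.table(chrom = "chr1", size = 15e6), 1e6)
  tr <- simulate_contact_counts(g, NULL, contact_config(seed = 3))
  sdv <- c(0.3, rep(0, 13), 0.3)
  out0 <- simulate_sd_mapping_bias(tr, sdv, list(c(1L, 15L)), relocation_rate = 0, seed = 9)
  expect_equal(out0[, .(i, j, count)], tr[, .(i, j, count)])
  out5 <- simulate_sd_mapping_bias(tr, sdv, list(c(1L, 15L)), relocation_rate = 0.5, seed = 9)
  expect_equal(sum(out5$count), sum(tr$count))
  expect_true(all(out5$sdr <= out5$count))
  expect_error(simulate_sd_mapping_bias(tr, sdv, list(), relocation_rate = 1.5), "\\[0, 1\\]")
})

test_that("bias inflates the distant SD-partner pair in expectation", {
  g <- build_locus_grid(data.table(chrom = "chr1", size = 25e6), 1e6)
  sdv <- c(0.3, rep(0, 23), 0.3)
  set.seed(11)
  gains <- replicate(30, {
    tr <- simulate_contact_counts(g, NULL, contact_config(sigma = 0.3, seed = sample.int(1e6, 1)))
    out <- simulate_sd_mapping_bias(tr, sdv, list(c(1L, 25L)), 0.5, seed = sample.int(1e6, 1))
    take <- function(x) { v <- x[i == 1 & j == 25, count]; if (length(v)) v else 0 }
    take(out) - take(tr)
  })
  expect_gt(mean(gains), 0)
})
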