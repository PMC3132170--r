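# Locus grid, filtering, binning, distances, SD correction.

test_that("grid tiles chromosomes, short last window, autosomes only", {
  g <- build_locus_grid(data.table(chrom = "chr1", size = 10e6), 1e6)
  expect_equal(nrow(g), 10L)
  g2 <- build_locus_grid(data.table(chrom = "chr1", size = 10.4e6), 1e6)
  expect_equal(nrow(g2), 11L)
  expect_equal(g2$end[11] - g2$start[11], 0.4e6)
  g3 <- build_locus_grid(data.table(chrom = c("chr1", "chrX", "chrY"),
                                    size = c(5e6, 5e6, 5e6)), 1e6)
  expect_equal(unique(g3$chrom), "chr1")
  # window longer than the chromosome: one short window, no error
  g4 <- build_locus_grid(data.table(chrom = "chr1", size = 0.3e6), 1e6)
  expect_equal(nrow(g4), 1L)
  expect_error(build_locus_grid(data.table(chrom = "chr1", size = 1e6), 1e6,
                                autosomes = character(0)), "autosome")
})

test_that("gap filter is strict at the 50% boundary", {
  g <- build_locus_grid(data.table(chrom = "chr1", size = 3e6), 1e6)
  g$gap_frac <- c(0.6, 0.5, 0)
  kept <- filter_loci(g)
  expect_equal(kept$idx, c(2L, 3L))
})

test_that("coverage fraction merges overlapping intervals", {
  g <- build_locus_grid(data.table(chrom = "chr1", size = 1e6), 1e6)
  sd <- data.table(chrom = "chr1", start = c(0, 50e3), end = c(100e3, 150e3))
  expect_equal(coverage_fraction(g, sd), 0.15)
  expect_equal(coverage_fraction(g, sd[0]), 0)
  full <- data.table(chrom = "chr1", start = 0, end = 1e6)
  expect_equal(coverage_fraction(g, full), 1.0)
  expect_equal(compute_sd_fraction(g, sd)$sd_frac, 0.15)
})

test_that("pair enumeration yields n(n+1)/2 unordered pairs including self-pairs", {
  g <- build_locus_grid(data.table(chrom = c("chr1", "chr2"), size = c(3e6, 2e6)), 1e6)
  ep <- enumerate_locus_pairs(g)
  expect_equal(nrow(ep), 5 * 6 / 2)
  expect_true(all(ep$i <= ep$j))
  expect_equal(nrow(unique(ep)), nrow(ep))
})

test_that("read-pair binning: floor division, self-pairs, conservation", {
  g <- build_locus_grid(data.table(chrom = "chr1", size = 5e6), 1e6)
  reads <- data.table(chrom1 = "chr1", pos1 = c(0.5e6, 1.2e6, 3.9e6, 0.1e6),
                      chrom2 = c("chr1", "chr1", "chr1", "chr9"),
                      pos2 = c(2.5e6, 1.8e6, 0.2e6, 1e6))
  out <- suppressMessages(bin_read_pairs(reads, g))
  expect_equal(out[i == 1 & j == 3, count], 1)   # 0.5 Mb with 2.5 Mb
  expect_equal(out[i == 2 & j == 2, count], 1)   # both ends in window 2
  expect_equal(out[i == 1 & j == 4, count], 1)
  expect_equal(sum(out$count) + attr(out, "discarded"), nrow(reads))
  expect_equal(attr(out, "discarded"), 1L)       # chr9 end
})

test_that("SD correction follows the retained-fraction estimator", {
  expect_equal(correct_pair_count(100, 20, 0.1, 0), 80 / 0.9)
  expect_equal(correct_pair_count(50, 0, 0, 0), 50)        # identity on SD-free pairs
  expect_equal(correct_pair_count(30, 30, 0.5, 0.5), 0)    # all reads SD-involved
  expect_warning(out <- correct_pair_count(10, 5, 1, 0), "undefined")
  expect_true(is.na(out))
  expect_error(correct_pair_count(10, 11, 0.1, 0.1), "SDR")
  # monotone non-decreasing in NR at fixed SDR, FSD
  nrs <- seq(20, 100, by = 5)
  vals <- correct_pair_count(nrs, 10, 0.2, 0.3)
  expect_true(all(diff(vals) >= 0))
})

test_that("genomic distance uses window starts, NA marks inter", {
  g <- build_locus_grid(data.table(chrom = c("chr1", "chr2"), size = c(10e6, 5e6)), 1e6)
  expect_equal(compute_genomic_distance(g, 4, 8), 4)
  expect_equal(compute_genomic_distance(g, 3, 3), 0)
  expect_true(is.na(compute_genomic_distance(g, 1, 11)))
})

test_that("pair_counts_from_triples joins counts, zero-fills, labels SDR mode", {
  g <- build_locus_grid(data.table(chrom = "chr1", size = 4e6), 1e6)
  g$sd_frac <- c(0.2, 0, 0, 0)
  trip <- data.table(i = c(1L, 2L), j = c(3L, 2L), count = c(10, 4), sdr = c(4, 0))
  pc <- pair_counts_from_triples(trip, g)
  expect_equal(nrow(pc), 10L)
  expect_equal(pc[i == 1 & j == 3, NR], 10)
  expect_equal(pc[i == 1 & j == 3, NRCSD], (10 - 4) / 0.8)
  expect_equal(pc[i == 2 & j == 2, NRCSD], 4)
  expect_equal(pc[i == 1 & j == 4, NR], 0)
  expect_equal(attr(pc, "sdr_mode"), "observed")
  # estimated mode is the algebraic identity, and is labelled
  pc2 <- pair_counts_from_triples(trip[, .(i, j, count)], g)
  expect_equal(attr(pc2, "sdr_mode"), "estimated")
  expect_equal(pc2[i == 1 & j == 3, NRCSD], 10)
})
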