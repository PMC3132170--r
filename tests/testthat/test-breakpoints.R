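# Breakpoint detection, pairing, reciprocal classification, origins.

make_order <- function(perm, chrom = "chr1", len = 1e6, spacer = 1e5) {
  starts <- spacer + (seq_along(perm) - 1) * (len + spacer)
  block_order(data.table(block_id = abs(perm), chrom = chrom,
                         start = starts, end = starts + len,
                         strand = ifelse(perm > 0, "+", "-")))
}

test_that("identical orders yield no internal breakpoint; telomeres optional", {
  oa <- make_order(1:4)
  bps <- find_breakpoints(oa, oa, include_telomeres = FALSE)
  expect_equal(nrow(bps), 0L)
  bps_t <- find_breakpoints(oa, oa, include_telomeres = TRUE)
  expect_equal(nrow(bps_t), 2L)
  expect_true(all(bps_t$is_telomere))
  expect_equal(bps_t$start, c(0, max(as.data.table(oa)$end)))
})

test_that("a single inverted block breaks both flanking adjacencies", {
  oa <- make_order(1:3)
  ob <- make_order(c(1L, -2L, 3L))
  for (pair in list(list(oa, ob), list(ob, oa))) {
    bps <- find_breakpoints(pair[[1]], pair[[2]], include_telomeres = FALSE)
    expect_equal(nrow(bps), 2L)
    expect_equal(bps$left_block, c(1L, 2L))
    expect_equal(bps$right_block, c(2L, 3L))
  }
  # a jointly reversed run is NOT a breakpoint
  ob2 <- make_order(c(-3L, -2L, -1L))
  expect_equal(nrow(find_breakpoints(oa, ob2, include_telomeres = FALSE)), 0L)
})

test_that("swapped blocks break the internal adjacency, telomeres are emitted", {
  oa <- make_order(1:2)
  ob <- make_order(c(2L, 1L))
  bps <- find_breakpoints(oa, ob, include_telomeres = TRUE)
  internal <- bps[is_telomere == FALSE]
  expect_equal(nrow(internal), 1L)
  expect_equal(c(internal$left_block, internal$right_block), c(1L, 2L))
  expect_equal(sum(bps$is_telomere), 2L)
})

test_that("mismatched block sets are rejected naming the id", {
  oa <- make_order(1:3)
  ob <- make_order(1:2)
  expect_error(find_breakpoints(oa, ob), "3")
  dup <- data.table(block_id = c(1, 1, 2), chrom = "chr1",
                    start = c(0, 2e6, 4e6), end = c(1e6, 3e6, 5e6), strand = "+")
  expect_error(block_order(dup), "duplicated block id")
})

test_that("simple inversion gives one merged pair with two linking breakpoints", {
  oa <- make_order(c(1L, -2L, 3L))
  ob <- make_order(1:3)
  bA <- find_breakpoints(oa, ob, genome = "A")
  bB <- find_breakpoints(ob, oa, genome = "B")
  pairs <- pair_breakpoints(bA, bB)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$n_links, 2L)
  expect_true(classify_reciprocal(pairs)$reciprocal)
  # symmetric in the two genomes
  pairs_rev <- pair_breakpoints(bB, bA)
  expect_equal(nrow(pairs_rev), 1L)
  expect_equal(pairs_rev$n_links, 2L)
})

test_that("inversion followed by translocation re-using a breakpoint gives two non-reciprocal pairs sharing a member", {
  pa <- spatialsynteny:::invert_segment(1:5, 2, 2)
  pa <- spatialsynteny:::translocate_block(pa, 3, 5)  # 1,-2,4,5,3
  oa <- make_order(pa)
  ob <- make_order(1:5)
  bA <- find_breakpoints(oa, ob, genome = "A")
  bB <- find_breakpoints(ob, oa, genome = "B")
  pairs <- classify_reciprocal(pair_breakpoints(bA, bB))
  expect_gte(nrow(pairs), 2L)
  members <- c(pairs$bp1, pairs$bp2)
  expect_true(any(table(members) > 1L))          # a shared breakpoint exists
  shared <- names(which(table(members) > 1L))
  sharing <- pairs[bp1 %in% shared | bp2 %in% shared]
  expect_true(all(!sharing$reciprocal))
})

test_that("zero genome-B breakpoints yield zero pairs", {
  oa <- make_order(1:3)
  bA <- find_breakpoints(oa, oa, genome = "A")
  bB <- find_breakpoints(oa, oa, genome = "B")
  expect_equal(nrow(pair_breakpoints(bA, bB)), 0L)
})

test_that("reciprocal classification follows membership, transitively", {
  chain <- data.table(bp1 = c("x", "y", "z"), bp2 = c("y", "z", "w"))
  expect_false(any(classify_reciprocal(chain)$reciprocal))
  isolated <- data.table(bp1 = c("x", "u"), bp2 = c("y", "v"))
  expect_true(all(classify_reciprocal(isolated)$reciprocal))
  # single linking breakpoint, no shared member -> still reciprocal
  one_link <- data.table(bp1 = "x", bp2 = "y", n_links = 1L)
  expect_true(classify_reciprocal(one_link)$reciprocal)
})

test_that("origin assignment implements the outgroup-parsimony truth table", {
  oa <- make_order(c(1L, -2L, 3L))
  ob <- make_order(1:3)
  bA <- find_breakpoints(oa, ob, genome = "A")
  bB <- find_breakpoints(ob, oa, genome = "B")
  partners <- breakpoint_partners(bA, bB)
  internal_A <- as.data.table(bA)[is_telomere == FALSE]
  internal_B <- as.data.table(bB)[is_telomere == FALSE]
  cover_A <- internal_A[, .(chrom, start, end)]
  cover_B <- internal_B[, .(chrom, start, end)]
  none <- data.table(chrom = "chrZ", start = 0, end = 1)
  get <- function(og_A, og_B) {
    o <- assign_breakpoint_origin(bA, partners, bB, og_A, og_B)
    o[bp_id %in% internal_A$bp_id, origin]
  }
  expect_equal(get(cover_A, none), rep("human", 2))       # hd yes, md no
  expect_equal(get(none, cover_B), rep("mouse", 2))       # hd no, md both yes
  expect_equal(get(cover_A, cover_B), rep("unknown", 2))  # contradictory
  expect_equal(get(none, none), rep("unknown", 2))        # no signal
})

test_that("pair origin requires agreement of both members", {
  pairs <- data.table(bp1 = c("a", "c", "e"), bp2 = c("b", "d", "f"))
  origins <- data.table(bp_id = letters[1:6],
                        origin = c("human", "human", "human", "mouse", "mouse", "unknown"))
  out <- assign_pair_origin(pairs, origins)
  expect_equal(out$origin, c("human", "unknown", "unknown"))
})

test_that("pairing properties hold on random scenarios", {
  set.seed(20260910)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    cfg <- scenario_config(n_blocks = n, block_length = 1e6, spacer = 1e5,
                           n_inversions_A = sample(0:2, 1), n_translocations_A = sample(0:1, 1),
                           n_inversions_B = sample(0:2, 1), n_translocations_B = sample(0:1, 1),
                           seed = sample.int(1e6, 1))
    sc <- simulate_rearrangement_scenario(cfg)
    oa <- sc$orders$human; ob <- sc$orders$mouse
    bA <- find_breakpoints(oa, ob, genome = "A")
    bB <- find_breakpoints(ob, oa, genome = "B")
    pairs <- classify_reciprocal(pair_breakpoints(bA, bB))
    # merged pairs bounded by the number of internal B breakpoints
    expect_lte(nrow(pairs), sum(!bB$is_telomere))
    # a reciprocal pair's members have degree 1 in the pair multigraph
    if (any(pairs$reciprocal)) {
      deg <- table(c(pairs$bp1, pairs$bp2))
      rec <- pairs[reciprocal == TRUE]
      expect_true(all(deg[c(rec$bp1, rec$bp2)] == 1L))
    }
  }
})
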