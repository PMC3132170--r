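# Simulation of two-lineage rearrangement histories with known breakpoint
# pairs and origins.
#
# Genomes are signed permutations of n oriented blocks on one chromosome; the
# ancestor is the identity and the outgroup retains it. Inversions reverse and
# flip a contiguous run of blocks; a translocation excises one block and
# reinserts it elsewhere (three-breakpoint, transposition-style events arise
# from this operator). Ground truth (breakpoints, pairs, reciprocal flags,
# lineage origins) is derived from the resulting permutations by brute-force
# adjacency enumeration — an independent code path from the coordinate-based
# detection in find_breakpoints()/pair_breakpoints(), which makes the
# simulator usable as an oracle for those functions.

#' Configuration of a rearrangement scenario
#'
#' @param n_blocks Number of syntenic blocks (>= 2; >= 3 if any event).
#' @param block_length Block length in bp.
#' @param n_inversions_A,n_translocations_A Events applied in lineage A
#'   ("human").
#' @param n_inversions_B,n_translocations_B Events applied in lineage B
#'   ("mouse").
#' @param spacer Inter-block spacer in bp; breakpoint regions are spacers, so
#'   it must be positive for origin overlap tests to be meaningful.
#' @param margin Telomeric margin in bp (default `spacer`).
#' @param seed Integer seed; all randomness flows from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_blocks = 40, block_length = 5e6,
                            n_inversions_A = 1, n_translocations_A = 1,
                            n_inversions_B = 1, n_translocations_B = 1,
                            spacer = 2e5, margin = NULL, seed = 1) {
  counts <- c(n_inversions_A, n_translocations_A, n_inversions_B, n_translocations_B)
  stop_if_not(all(vapply(counts, is_count, logical(1))), "event counts must be non-negative integers")
  stop_if_not(is_count(n_blocks) && n_blocks >= 2, "n_blocks must be an integer >= 2")
  stop_if_not(sum(counts) == 0 || n_blocks >= 3, "n_blocks must be >= 3 when any event is simulated")
  per_lineage <- c(A = n_inversions_A + n_translocations_A, B = n_inversions_B + n_translocations_B)
  too_big <- per_lineage > n_blocks - 1
  stop_if_not(!any(too_big),
              "event count too large: lineage %s has %d events but only %d blocks allow at most %d",
              names(per_lineage)[too_big][1], per_lineage[too_big][1], n_blocks, n_blocks - 1)
  stop_if_not(block_length > 0 && spacer > 0, "block_length and spacer must be positive")
  structure(list(n_blocks = as.integer(n_blocks), block_length = block_length,
                 n_inversions_A = n_inversions_A, n_translocations_A = n_translocations_A,
                 n_inversions_B = n_inversions_B, n_translocations_B = n_translocations_B,
                 spacer = spacer, margin = margin %||% spacer, seed = seed),
            class = "scenario_config")
}

# -- event operators on signed permutations ---------------------------------

invert_segment <- function(perm, i, j) {
  perm[i:j] <- -rev(perm[i:j])
  perm
}

translocate_block <- function(perm, p, g) {
  # excise block at position p, reinsert after the g-th remaining block
  blk <- perm[p]
  rest <- perm[-p]
  append(rest, blk, after = g)
}

random_event <- function(perm, type) {
  n <- length(perm)
  if (type == "inversion") {
    i <- sample.int(n, 1L)
    j <- sample(i:n, 1L)
    list(type = "inversion", i = i, j = j, perm = invert_segment(perm, i, j))
  } else {
    repeat {
      p <- sample.int(n, 1L)
      g <- sample(0:(n - 1L), 1L)
      if (g != p - 1L) break  # reinserting in place is a no-op
    }
    list(type = "translocation", i = p, j = g, perm = translocate_block(perm, p, g))
  }
}

# -- brute-force adjacency enumeration (the oracle) -------------------------

#' Breakpoint positions between two signed permutations (brute force)
#'
#' Position `p` (in `1..n-1`) is a breakpoint on `pa` iff blocks `pa[p]`,
#' `pa[p+1]` are not adjacent with the same relative orientation in `pb`.
#' Naive search by definition; serves as the reference implementation for
#' [find_breakpoints()].
#'
#' @param pa,pb Signed permutations of the same block set.
#' @return Sorted integer vector of broken positions.
#' @export
perm_breakpoints <- function(pa, pb) {
  n <- length(pa)
  out <- integer(0)
  for (p in seq_len(n - 1L)) {
    u <- pa[p]; v <- pa[p + 1L]
    q <- which(abs(pb) == abs(u))
    conserved <- if (pb[q] == u) q < n && pb[q + 1L] == v else q > 1L && pb[q - 1L] == -v
    if (!conserved) out <- c(out, p)
  }
  out
}

# Break position on `other` adjacent to the facing extremity of signed block
# `s`. `side = "right"`: the extremity on s's right as laid in the source
# genome; `side = "left"`: on its left. Returns a position in 0..n (0 and n
# are telomeres of `other`).
perm_partner_pos <- function(other, s, side) {
  r <- which(abs(other) == abs(s))
  same <- other[r] == s
  if (side == "right") { if (same) r else r - 1L } else { if (same) r - 1L else r }
}

#' Breakpoint pairs between two signed permutations (brute force)
#'
#' For every internal breakpoint of `pb` (vs `pa`), locates the two `pa`
#' breakpoints orthologous to the facing extremities of its flanking blocks,
#' merges duplicate candidate pairs, classifies reciprocity by membership, and
#' (when an outgroup permutation is given) assigns lineage origins by the
#' outgroup-parsimony rule. Positions `0` and `n` denote telomeres.
#'
#' @param pa,pb Signed permutations of the same block set.
#' @param po Optional outgroup permutation.
#' @return `data.table(pos1, pos2, n_links, linking, reciprocal, origin)`
#'   where positions index `pa` (pair members) and `linking` holds `pb`
#'   breakpoint positions.
#' @export
perm_breakpoint_pairs <- function(pa, pb, po = NULL) {
  brB <- perm_breakpoints(pb, pa)
  cand <- lapply(brB, function(q) {
    u <- pb[q]; v <- pb[q + 1L]
    p1 <- perm_partner_pos(pa, u, "right")
    p2 <- perm_partner_pos(pa, v, "left")
    stop_if_not(p1 != p2, "degenerate candidate pair at pb position %d", q)
    data.table(pos1 = min(p1, p2), pos2 = max(p1, p2), link = q)
  })
  if (length(cand) == 0L) {
    return(data.table(pos1 = integer(), pos2 = integer(), n_links = integer(),
                      linking = character(), reciprocal = logical(), origin = character()))
  }
  cand <- rbindlist(cand)
  pairs <- cand[, .(n_links = .N, linking = paste(sort(link), collapse = ",")),
                by = .(pos1, pos2)]
  deg <- table(c(pairs$pos1, pairs$pos2))
  pairs[, reciprocal := deg[as.character(pos1)] == 1L & deg[as.character(pos2)] == 1L]
  if (!is.null(po)) {
    brAO <- perm_breakpoints(pa, po)
    brBO <- perm_breakpoints(pb, po)
    origin_of <- function(p) {
      n <- length(pa)
      if (p == 0L || p == n) return("unknown")  # telomere sentinel
      u <- pa[p]; v <- pa[p + 1L]
      bm1 <- perm_partner_pos(pb, u, "right")
      bm2 <- perm_partner_pos(pb, v, "left")
      in_ao <- p %in% brAO
      m1 <- bm1 %in% brBO  # telomeres (0, n) are never in brBO
      m2 <- bm2 %in% brBO
      if (in_ao && !m1 && !m2) "human"
      else if (!in_ao && m1 && m2) "mouse"
      else "unknown"
    }
    o1 <- vapply(pairs$pos1, origin_of, character(1))
    o2 <- vapply(pairs$pos2, origin_of, character(1))
    pairs[, origin := ifelse(o1 == o2 & o1 != "unknown", o1, "unknown")]
  } else {
    pairs[, origin := "unknown"]
  }
  setorder(pairs, pos1, pos2)
  pairs[]
}

# -- coordinates ------------------------------------------------------------

# lay a signed permutation out on one chromosome as a block_order
layout_order <- function(perm, cfg, chrom = "chr1") {
  n <- length(perm)
  starts <- cfg$margin + (seq_len(n) - 1L) * (cfg$block_length + cfg$spacer)
  block_order(data.table(
    block_id = abs(perm), chrom = chrom,
    start = starts, end = starts + cfg$block_length,
    strand = ifelse(perm > 0, "+", "-")
  ))
}

genome_length <- function(cfg) {
  2 * cfg$margin + cfg$n_blocks * cfg$block_length + (cfg$n_blocks - 1L) * cfg$spacer
}

# interval of break position p (0..n) on the laid-out genome
break_interval <- function(p, cfg) {
  step <- cfg$block_length + cfg$spacer
  n <- cfg$n_blocks
  if (p == 0L) c(0, 0)
  else if (p == n) rep(cfg$margin + (n - 1L) * step + cfg$block_length, 2L)
  else c(cfg$margin + (p - 1L) * step + cfg$block_length, cfg$margin + p * step)
}

#' Simulate a two-lineage rearrangement scenario with ground truth
#'
#' Applies the configured inversions and translocations (in shuffled order per
#' lineage) to an ancestral identity order; the outgroup keeps the ancestral
#' order. Ground-truth breakpoints, pairs, reciprocal flags and origins are
#' derived from the resulting permutations by [perm_breakpoint_pairs()], with
#' the outgroup standing in for the ancestor in the parsimony rule.
#'
#' @param cfg A [scenario_config()].
#' @return A `rearrangement_scenario` list: `config`; `perms` (`A`, `B`, `O`);
#'   `orders` (`human`, `mouse`, `outgroup` [block_order()]s with cumulative
#'   coordinates); `events` log; `truth_pairs` (pair table with permutation
#'   positions, human-genome coordinates of both members, `reciprocal`,
#'   `origin`); `n_internal_breakpoints` per genome.
#' @export
simulate_rearrangement_scenario <- function(cfg) {
  stop_if_not(inherits(cfg, "scenario_config"), "cfg must be a scenario_config")
  n <- cfg$n_blocks
  with_seed(cfg$seed, {
    anc <- seq_len(n)
    ev_types <- list(
      A = sample(c(rep("inversion", cfg$n_inversions_A), rep("translocation", cfg$n_translocations_A))),
      B = sample(c(rep("inversion", cfg$n_inversions_B), rep("translocation", cfg$n_translocations_B)))
    )
    perms <- list(A = anc, B = anc)
    events <- list()
    for (lin in c("A", "B")) {
      for (type in ev_types[[lin]]) {
        ev <- random_event(perms[[lin]], type)
        perms[[lin]] <- ev$perm
        events[[length(events) + 1L]] <- data.table(
          lineage = lin, type = ev$type, param1 = ev$i, param2 = ev$j)
      }
    }
    events <- if (length(events)) rbindlist(events) else
      data.table(lineage = character(), type = character(), param1 = integer(), param2 = integer())
    build_scenario(cfg, perms$A, perms$B, anc, events)
  })
}

# assemble a scenario object from explicit permutations (also used by tests)
build_scenario <- function(cfg, pa, pb, po, events = NULL) {
  truth <- perm_breakpoint_pairs(pa, pb, po)
  coords <- function(p) t(vapply(p, break_interval, numeric(2), cfg = cfg))
  if (nrow(truth)) {
    c1 <- coords(truth$pos1); c2 <- coords(truth$pos2)
    truth[, `:=`(bp1_chrom = "chr1", bp1_start = c1[, 1], bp1_end = c1[, 2],
                 bp2_chrom = "chr1", bp2_start = c2[, 1], bp2_end = c2[, 2])]
  } else {
    truth[, `:=`(bp1_chrom = character(), bp1_start = numeric(), bp1_end = numeric(),
                 bp2_chrom = character(), bp2_start = numeric(), bp2_end = numeric())]
  }
  structure(list(
    config = cfg,
    perms = list(A = pa, B = pb, O = po),
    orders = list(human = layout_order(pa, cfg), mouse = layout_order(pb, cfg),
                  outgroup = layout_order(po, cfg)),
    events = events,
    truth_pairs = truth,
    n_internal_breakpoints = c(A = length(perm_breakpoints(pa, pb)),
                               B = length(perm_breakpoints(pb, pa)))
  ), class = "rearrangement_scenario")
}

#' @export
print.rearrangement_scenario <- function(x, ...) {
  cat(sprintf("Rearrangement scenario: %d blocks, %d events; %d/%d internal breakpoints (A/B); %d truth pairs (%d reciprocal)\n",
              x$config$n_blocks, if (is.null(x$events)) 0L else nrow(x$events),
              x$n_internal_breakpoints["A"], x$n_internal_breakpoints["B"],
              nrow(x$truth_pairs), sum(x$truth_pairs$reciprocal)))
  invisible(x)
}
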