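# Breakpoint detection, pairing, reciprocal classification and lineage-of-origin
# assignment from synteny-block orders.
#
# A breakpoint is the region between two consecutive synteny blocks on one
# genome whose orthologous blocks on the other genome are not consecutive, or
# not in the same relative orientation. Because each breakpoint is flanked by
# two blocks, it is orthologous at its extremities to two breakpoints on the
# other genome; each genome-B breakpoint therefore links two genome-A
# breakpoints into a candidate pair (distant on A, adjacent on B). Pairs whose
# two members appear in no other pair are reciprocal (signature of one simple
# inversion/translocation); shared members mark non-reciprocal pairs
# (breakpoint re-use or complex series of events).
#
# Orientation bookkeeping uses block extremities: block b has tail 2b-1 and
# head 2b; an adjacency between consecutive blocks is the unordered pair of the
# facing extremities, so a jointly inverted run of blocks is not a breakpoint.

#' Construct a per-genome synteny block order
#'
#' @param x data.frame with columns `block_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`).
#' @return A `block_order` (`data.table`) sorted by (chrom, start).
#' @export
block_order <- function(x) {
  dt <- as.data.table(x)
  need <- c("block_id", "chrom", "start", "end", "strand")
  missing <- setdiff(need, names(dt))
  stop_if_not(length(missing) == 0L, "block order lacks column(s): %s",
              paste(missing, collapse = ", "))
  dt <- dt[, need, with = FALSE]
  dup <- dt$block_id[duplicated(dt$block_id)]
  stop_if_not(length(dup) == 0L, "duplicated block id(s): %s",
              paste(unique(dup), collapse = ", "))
  stop_if_not(all(dt$strand %in% c("+", "-")), "strand must be '+' or '-'")
  stop_if_not(all(dt$start < dt$end), "blocks must have start < end")
  setorder(dt, chrom, start)
  overl <- dt[, any(head(end, -1L) > tail(start, -1L)), by = chrom][, any(V1)]
  stop_if_not(!overl, "blocks overlap within a chromosome")
  setattr(dt, "class", c("block_order", class(dt)))
  dt
}

# signed blocks per chromosome, reading left to right
signed_blocks <- function(order) {
  dt <- as.data.table(order)
  split(ifelse(dt$strand == "+", 1L, -1L) * as.integer(dt$block_id), dt$chrom)
}

ext_left <- function(s) ifelse(s > 0L, 2L * s - 1L, -2L * s)   # tail if +, head if -
ext_right <- function(s) ifelse(s > 0L, 2L * s, -2L * s - 1L)  # head if +, tail if -
adj_key <- function(e1, e2) paste0(pmin(e1, e2), "_", pmax(e1, e2))

# all internal adjacency keys of an order
adjacency_keys <- function(order) {
  segs <- signed_blocks(order)
  unlist(lapply(segs, function(v) {
    if (length(v) < 2L) character(0)
    else adj_key(ext_right(v[-length(v)]), ext_left(v[-1L]))
  }), use.names = FALSE)
}

check_same_blocks <- function(orderA, orderB) {
  a <- as.data.table(orderA)$block_id
  b <- as.data.table(orderB)$block_id
  onlyA <- setdiff(a, b)
  onlyB <- setdiff(b, a)
  stop_if_not(length(onlyA) == 0L && length(onlyB) == 0L,
              "block id(s) present in one genome only: %s",
              paste(c(onlyA, onlyB), collapse = ", "))
}

#' Identify breakpoints on genome A relative to genome B
#'
#' Emits one breakpoint per broken adjacency: the interval between the end of
#' the left flanking block and the start of the right one. An adjacency is
#' conserved when the same unordered pair of block extremities is adjacent on
#' the other genome, so jointly inverted runs of blocks do not break. With
#' `include_telomeres`, chromosome extremities are emitted as zero-length
#' sentinel breakpoints (at position 0 and at the end of the last block); they
#' have a single flanking block and participate in pairing but never in
#' origin-overlap tests.
#'
#' @param orderA,orderB [block_order()] objects over the same block ids.
#' @param include_telomeres Emit telomere sentinels (default `TRUE`).
#' @param genome Label stored in ids (default `"A"`).
#' @return A `breakpoint_set`: `data.table(bp_id, chrom, start, end,
#'   left_block, right_block, is_telomere, e1, e2)` where `e1`/`e2` are the
#'   facing block extremities (`e2` is `NA` for telomeres). Carries an
#'   extremity-to-breakpoint lookup used by [pair_breakpoints()].
#' @export
find_breakpoints <- function(orderA, orderB, include_telomeres = TRUE, genome = "A") {
  check_same_blocks(orderA, orderB)
  adjB <- adjacency_keys(orderB)
  dtA <- as.data.table(orderA)
  segs <- signed_blocks(orderA)
  rows <- list()
  for (ch in names(segs)) {
    v <- segs[[ch]]
    blk <- dtA[chrom == ch]
    n <- length(v)
    if (n >= 2L) {
      er <- ext_right(v[-n]); el <- ext_left(v[-1L])
      broken <- !(adj_key(er, el) %in% adjB)
      if (any(broken)) {
        p <- which(broken)
        rows[[length(rows) + 1L]] <- data.table(
          bp_id = sprintf("%s:%s:%d-%d", genome, ch, blk$end[p], blk$start[p + 1L]),
          chrom = ch, start = blk$end[p], end = blk$start[p + 1L],
          left_block = abs(v[p]), right_block = abs(v[p + 1L]),
          is_telomere = FALSE, e1 = er[p], e2 = el[p]
        )
      }
    }
    if (include_telomeres) {
      rows[[length(rows) + 1L]] <- data.table(
        bp_id = c(sprintf("%s:%s:telL", genome, ch), sprintf("%s:%s:telR", genome, ch)),
        chrom = ch,
        start = c(0, blk$end[n]), end = c(0, blk$end[n]),
        left_block = c(NA_integer_, abs(v[n])),
        right_block = c(abs(v[1L]), NA_integer_),
        is_telomere = TRUE,
        e1 = c(ext_left(v[1L]), ext_right(v[n])), e2 = NA_integer_
      )
    }
  }
  bps <- if (length(rows)) rbindlist(rows) else data.table(
    bp_id = character(), chrom = character(), start = numeric(), end = numeric(),
    left_block = integer(), right_block = integer(), is_telomere = logical(),
    e1 = integer(), e2 = integer()
  )
  setorder(bps, chrom, start, end, bp_id)
  ext_map <- c(
    setNames(bps$bp_id, as.character(bps$e1)),
    setNames(bps$bp_id[!bps$is_telomere], as.character(bps$e2[!bps$is_telomere]))
  )
  setattr(bps, "genome", genome)
  setattr(bps, "ext_map", ext_map)
  setattr(bps, "class", c("breakpoint_set", class(bps)))
  bps
}

#' Group genome-A breakpoints into pairs via genome-B adjacency
#'
#' Each non-telomeric genome-B breakpoint is flanked by two blocks whose facing
#' extremities identify, on genome A, the two breakpoints it links. Candidate
#' pairs with the same unordered member set are merged, recording every linking
#' B breakpoint (a single simple inversion yields the same pair from both of
#' its B breakpoints).
#'
#' @param bps_A,bps_B [find_breakpoints()] results for the two directions
#'   (A-vs-B and B-vs-A).
#' @return A `breakpoint_pairs` `data.table`: `pair_id, bp1, bp2, linking,
#'   n_links` plus the members' coordinates; `bp1 < bp2` by (chrom, start).
#' @export
pair_breakpoints <- function(bps_A, bps_B) {
  extA <- attr(bps_A, "ext_map")
  internal <- as.data.table(bps_B)[is_telomere == FALSE]
  empty <- data.table(
    pair_id = character(), bp1 = character(), bp2 = character(),
    linking = character(), n_links = integer()
  )
  if (nrow(internal) == 0L) {
    pairs <- cbind(empty,
                   data.table(bp1_chrom = character(), bp1_start = numeric(), bp1_end = numeric(),
                              bp1_telomere = logical(), bp2_chrom = character(),
                              bp2_start = numeric(), bp2_end = numeric(), bp2_telomere = logical()))
    setattr(pairs, "class", c("breakpoint_pairs", class(pairs)))
    return(pairs)
  }
  p1 <- extA[as.character(internal$e1)]
  p2 <- extA[as.character(internal$e2)]
  bad <- is.na(p1) | is.na(p2)
  if (any(bad)) {
    stop(sprintf(
      "genome-B breakpoint(s) %s have a flanking block extremity with no breakpoint on genome A (was find_breakpoints run with include_telomeres and the same block set?)",
      paste(internal$bp_id[bad], collapse = ", ")), call. = FALSE)
  }
  # deterministic member order: by (chrom, start, end, id) on genome A
  akey <- as.data.table(bps_A)[, .(bp_id, chrom, start, end)]
  ord <- setNames(seq_len(nrow(akey)), akey$bp_id)  # akey is sorted
  swap <- ord[p2] < ord[p1]
  cand <- data.table(
    bp1 = ifelse(swap, p2, p1),
    bp2 = ifelse(swap, p1, p2),
    link = internal$bp_id
  )
  degen <- cand$bp1 == cand$bp2
  if (any(degen)) {
    warning(sprintf("dropping %d degenerate candidate pair(s) whose two members coincide", sum(degen)))
    cand <- cand[!degen]
  }
  pairs <- cand[, .(linking = paste(sort(link), collapse = ","), n_links = .N), by = .(bp1, bp2)]
  pairs[, pair_id := sprintf("P%03d", .I)]
  coords <- as.data.table(bps_A)[, .(bp_id, chrom, start, end, is_telomere)]
  pairs <- merge(pairs, setNames(coords, c("bp1", "bp1_chrom", "bp1_start", "bp1_end", "bp1_telomere")),
                 by = "bp1", all.x = TRUE)
  pairs <- merge(pairs, setNames(coords, c("bp2", "bp2_chrom", "bp2_start", "bp2_end", "bp2_telomere")),
                 by = "bp2", all.x = TRUE)
  setcolorder(pairs, c("pair_id", "bp1", "bp2", "linking", "n_links"))
  setorder(pairs, bp1_chrom, bp1_start, bp2_chrom, bp2_start, pair_id)
  setattr(pairs, "class", c("breakpoint_pairs", class(pairs)))
  pairs
}

#' Flag reciprocal breakpoint pairs
#'
#' A pair is reciprocal iff neither member occurs in any other pair; such pairs
#' are the signature of a single simple rearrangement. Classification is
#' membership-based: link multiplicity within one pair does not matter.
#'
#' @param pairs [pair_breakpoints()] result.
#' @return `pairs` with a logical `reciprocal` column added.
#' @export
classify_reciprocal <- function(pairs) {
  pairs <- copy(as.data.table(pairs))
  members <- c(pairs$bp1, pairs$bp2)
  deg <- table(members)
  pairs[, reciprocal := deg[bp1] == 1L & deg[bp2] == 1L]
  setattr(pairs, "class", unique(c("breakpoint_pairs", class(pairs))))
  pairs[]
}

#' Locate each genome-A breakpoint's two partner breakpoints on genome B
#'
#' The partners `Bm1`, `Bm2` of a genome-A breakpoint are the genome-B
#' breakpoints adjacent to the facing extremities of its flanking blocks
#' (block-extremity orthology). Telomere breakpoints have a single partner.
#'
#' @param bps_A,bps_B [find_breakpoints()] results for the two directions.
#' @return `data.table(bp_id, partner1, partner2)` (`NA` where absent).
#' @export
breakpoint_partners <- function(bps_A, bps_B) {
  extB <- attr(bps_B, "ext_map")
  dt <- as.data.table(bps_A)
  data.table(
    bp_id = dt$bp_id,
    partner1 = unname(extB[as.character(dt$e1)]),
    partner2 = unname(extB[as.character(dt$e2)])
  )
}

overlaps_any <- function(dt, target_gr) {
  # >= 1 bp intersection; zero-width records (telomere sentinels) never overlap
  if (nrow(dt) == 0L) return(logical(0))
  widthless <- dt$end <= dt$start
  out <- logical(nrow(dt))
  if (any(!widthless) && length(target_gr) > 0L) {
    gr <- dt0_to_granges(dt[!widthless])
    # differing seqlevel sets between query and target are expected, not an error
    out[!widthless] <- suppressWarnings(
      IRanges::overlapsAny(gr, GenomicRanges::reduce(target_gr)))
  }
  out
}

#' Assign a lineage of origin to each genome-A breakpoint using an outgroup
#'
#' With human = genome A, mouse = genome B and an outgroup (e.g. dog): a human
#' breakpoint gets origin `human` iff it overlaps a human-outgroup breakpoint
#' and neither of its mouse partners overlaps a mouse-outgroup breakpoint;
#' origin `mouse` iff it overlaps no human-outgroup breakpoint and both mouse
#' partners each overlap a mouse-outgroup breakpoint; otherwise `unknown`
#' (outgroup parsimony). Overlap means an intersection of at least 1 bp, so
#' zero-length telomere sentinels never satisfy an overlap condition.
#'
#' @param bps_A Genome-A (human) `breakpoint_set`.
#' @param partners [breakpoint_partners()] table for `bps_A` against genome B.
#' @param bps_B Genome-B (mouse) `breakpoint_set` (coordinates of partners).
#' @param outgroup_A Intervals of genome-A-vs-outgroup breakpoints on genome A
#'   (`GRanges` or 0-based `chrom`/`start`/`end` data.frame).
#' @param outgroup_B Same for genome B, on genome-B coordinates.
#' @return `data.table(bp_id, origin)` with origin in
#'   `c("human", "mouse", "unknown")` (genome-A / genome-B lineage).
#' @export
assign_breakpoint_origin <- function(bps_A, partners, bps_B, outgroup_A, outgroup_B) {
  as_gr <- function(x) if (is(x, "GRanges")) x else dt0_to_granges(as.data.table(x))
  dtA <- as.data.table(bps_A)
  dtB <- as.data.table(bps_B)
  partners <- as.data.table(partners)
  miss <- setdiff(dtA$bp_id, partners$bp_id)
  stop_if_not(length(miss) == 0L, "missing partner references for breakpoint(s): %s",
              paste(miss, collapse = ", "))
  ogA <- as_gr(outgroup_A)
  ogB <- as_gr(outgroup_B)
  ovA <- setNames(overlaps_any(dtA, ogA), dtA$bp_id)
  ovB <- setNames(overlaps_any(dtB, ogB), dtB$bp_id)
  p <- partners[match(dtA$bp_id, partners$bp_id)]
  ov1 <- ifelse(is.na(p$partner1), FALSE, ovB[p$partner1])
  ov2 <- ifelse(is.na(p$partner2), FALSE, ovB[p$partner2])
  has_both <- !is.na(p$partner1) & !is.na(p$partner2)
  origin <- rep("unknown", nrow(dtA))
  origin[ovA[dtA$bp_id] & !ov1 & !ov2] <- "human"
  origin[!ovA[dtA$bp_id] & has_both & ov1 & ov2] <- "mouse"
  data.table(bp_id = dtA$bp_id, origin = origin)
}

#' Assign an origin to breakpoint pairs
#'
#' A pair inherits an origin only when both members were assigned the same,
#' non-`unknown` origin.
#'
#' @param pairs `breakpoint_pairs`.
#' @param origins [assign_breakpoint_origin()] result.
#' @return `pairs` with an `origin` column.
#' @export
assign_pair_origin <- function(pairs, origins) {
  pairs <- copy(as.data.table(pairs))
  o <- setNames(origins$origin, origins$bp_id)
  o1 <- o[pairs$bp1]; o2 <- o[pairs$bp2]
  pairs[, origin := as.character(ifelse(!is.na(o1) & !is.na(o2) & o1 == o2 & o1 != "unknown",
                                        o1, "unknown"))]
  setattr(pairs, "class", unique(c("breakpoint_pairs", class(pairs))))
  pairs[]
}

#' Detect, pair, classify and (optionally) assign origins in one call
#'
#' @param orders_AB List of [block_order()]s `A`, `B` for the focal comparison.
#' @param outgroup_A,outgroup_B Optional outgroup breakpoint intervals on
#'   genome A and genome B (see [assign_breakpoint_origin()]); both must be
#'   given for origins to be assigned.
#' @param include_telomeres Passed to [find_breakpoints()].
#' @return `breakpoint_pairs` with `reciprocal` and `origin` columns, plus
#'   attributes `bps_A`, `bps_B`, `origins`.
#' @export
call_breakpoint_pairs <- function(orders_AB, outgroup_A = NULL, outgroup_B = NULL,
                                  include_telomeres = TRUE) {
  bps_A <- find_breakpoints(orders_AB$A, orders_AB$B, include_telomeres, genome = "A")
  bps_B <- find_breakpoints(orders_AB$B, orders_AB$A, include_telomeres, genome = "B")
  pairs <- classify_reciprocal(pair_breakpoints(bps_A, bps_B))
  origins <- NULL
  if (!is.null(outgroup_A) && !is.null(outgroup_B)) {
    partners <- breakpoint_partners(bps_A, bps_B)
    origins <- assign_breakpoint_origin(bps_A, partners, bps_B, outgroup_A, outgroup_B)
    pairs <- assign_pair_origin(pairs, origins)
  } else {
    pairs[, origin := "unknown"]
  }
  setattr(pairs, "bps_A", bps_A)
  setattr(pairs, "bps_B", bps_B)
  setattr(pairs, "origins", origins)
  pairs
}

#' Write a breakpoint-pair table
#'
#' Mirrors the layout of a published pair table: coordinates of both members,
#' origin, type (`R`/`NR`) and a used flag.
#'
#' @param pairs `breakpoint_pairs` with `reciprocal` (and optionally `origin`).
#' @param path Output TSV path.
#' @export
write_pair_table <- function(pairs, path) {
  dt <- as.data.table(pairs)
  out <- dt[, .(
    chrom1 = bp1_chrom, start1 = bp1_start, end1 = bp1_end,
    chrom2 = bp2_chrom, start2 = bp2_start, end2 = bp2_end,
    origin = if ("origin" %in% names(dt)) origin else "unknown",
    type = ifelse(reciprocal, "R", "NR"),
    used = "yes"
  )]
  fwrite(out, path, sep = "\t")
  invisible(path)
}
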