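# Binning of Hi-C read pairs, locus-pair enumeration, genomic distance, and
# the segmental-duplication mapping-bias correction of pair read counts.
#
# The correction discards reads with at least one end inside a segmental
# duplication (SDR) and rescales the remainder to the full-window expectation
# under the assumption that read density inside an SD equals that of the
# surrounding sequence: NRCSD = (NR - SDR) / ((1 - FSD1) * (1 - FSD2)).

#' Enumerate unordered locus pairs over a grid
#'
#' Includes self-pairs, so `n` retained windows yield `n(n+1)/2` pairs.
#'
#' @param grid A `locus_grid`, or a single integer number of loci.
#' @return `data.table(i, j)` with `i <= j` (values are grid `idx`).
#' @export
enumerate_locus_pairs <- function(grid) {
  idx <- if (is.numeric(grid) && length(grid) == 1L) seq_len(grid) else as.data.table(grid)$idx
  n <- length(idx)
  # row-wise expansion: pair (idx[a], idx[b]) for a <= b
  a <- rep.int(seq_len(n), times = n:1)
  b <- sequence(n:1) + a - 1L
  data.table(i = idx[a], j = idx[b])
}

#' Bin read pairs into window-pair counts
#'
#' Each read pair increments exactly one unordered window pair (self-pairs
#' allowed). Ends that fall outside the grid — unknown chromosome, position
#' out of bounds, or a filtered-out window — send the pair to a discard
#' bucket, reported in the `discarded` attribute.
#'
#' @param reads `data.table(chrom1, pos1, chrom2, pos2)` of read-end positions
#'   (0-based bp).
#' @param grid A `locus_grid` (possibly filtered).
#' @return `data.table(i, j, count)` with `i <= j`; attribute `discarded`
#'   holds the number of dropped read pairs.
#' @export
bin_read_pairs <- function(reads, grid) {
  reads <- as.data.table(reads)
  wl <- attr(grid, "window_length")
  gdt <- as.data.table(grid)
  key <- setNames(gdt$idx, sprintf("%s:%.0f", gdt$chrom, gdt$start))
  locate <- function(chrom, pos) {
    w <- floor(pos / wl) * wl
    unname(key[sprintf("%s:%.0f", chrom, w)])
  }
  i <- locate(reads$chrom1, reads$pos1)
  j <- locate(reads$chrom2, reads$pos2)
  ok <- !is.na(i) & !is.na(j) & reads$pos1 >= 0 & reads$pos2 >= 0
  n_disc <- sum(!ok)
  if (n_disc > 0L) message(sprintf("bin_read_pairs: %d read pair(s) discarded (outside grid)", n_disc))
  dt <- data.table(i = pmin(i[ok], j[ok]), j = pmax(i[ok], j[ok]))
  out <- dt[, .(count = as.numeric(.N)), by = .(i, j)]
  setorder(out, i, j)
  setattr(out, "discarded", n_disc)
  out[]
}

#' Genomic distance between windows
#'
#' Same chromosome: `|start_i - start_j| / 1e6` Mb (adjacent 1-Mb windows are
#' at distance 1; a self-pair is at 0). Different chromosomes: `NA` (the
#' inter-chromosomal marker).
#'
#' @param grid A `locus_grid`.
#' @param i,j Window indices (grid `idx`), recycled.
#' @return Numeric vector of distances in Mb, `NA` for inter-chromosomal.
#' @export
compute_genomic_distance <- function(grid, i, j) {
  gdt <- as.data.table(grid)
  ri <- match(i, gdt$idx); rj <- match(j, gdt$idx)
  stop_if_not(!anyNA(ri) && !anyNA(rj), "window index not in grid")
  ifelse(gdt$chrom[ri] == gdt$chrom[rj],
         abs(gdt$start[ri] - gdt$start[rj]) / 1e6,
         NA_real_)
}

#' Segmental-duplication correction of a pair read count
#'
#' `NRCSD = (NR - SDR) / ((1 - FSD1) * (1 - FSD2))`: reads touching an SD are
#' discarded and the remainder is rescaled to the whole window pair under the
#' uniform-density assumption. A window entirely covered by SDs (`FSD >= 1`)
#' leaves the correction undefined; such pairs get `NA` with a warning.
#'
#' @param NR Raw pair read counts.
#' @param SDR Counts of reads with at least one end in an SD (`0 <= SDR <= NR`).
#' @param FSD1,FSD2 SD fractions of the two windows, in `[0, 1]`.
#' @return Corrected counts (numeric, `NA` where undefined).
#' @export
correct_pair_count <- function(NR, SDR, FSD1, FSD2) {
  stop_if_not(all(SDR >= 0 & SDR <= NR), "SDR must satisfy 0 <= SDR <= NR")
  stop_if_not(all(FSD1 >= 0 & FSD1 <= 1 & FSD2 >= 0 & FSD2 <= 1),
              "FSD fractions must lie in [0, 1]")
  denom <- (1 - FSD1) * (1 - FSD2)
  bad <- denom <= 0
  if (any(bad)) {
    warning(sprintf("%d pair(s) with a window entirely covered by SDs: corrected count undefined", sum(bad)))
  }
  out <- (NR - SDR) / denom
  out[bad] <- NA_real_
  out
}

#' Build the full pair-count table from sparse triples
#'
#' Enumerates every unordered pair of retained windows, joins the observed
#' counts (absent pairs get 0), computes genomic distance and applies the SD
#' correction. When the triples carry no `sdr` column, SDR is estimated as
#' `NR * (1 - (1-FSD1)(1-FSD2))` under the uniformity assumption — note that
#' this estimate makes the correction the identity, so read-level or
#' simulator-provided SDR is required for the correction to have any effect;
#' the mode used is recorded in the `sdr_mode` attribute.
#'
#' @param triples `data.table(i, j, count[, sdr])`, 1-based indices into `grid`.
#' @param grid A (filtered) `locus_grid`; its `sd_frac` supplies FSD.
#' @return A `pair_counts` `data.table(i, j, chrom_i, chrom_j, GD, inter, NR,
#'   SDR, NRCSD)`.
#' @export
pair_counts_from_triples <- function(triples, grid) {
  gdt <- as.data.table(grid)
  triples <- as.data.table(triples)
  stray <- triples[!(i %in% gdt$idx) | !(j %in% gdt$idx)]
  if (nrow(stray) > 0L) {
    message(sprintf("pair_counts_from_triples: dropping %d triple(s) on filtered-out or unknown windows", nrow(stray)))
    triples <- triples[(i %in% gdt$idx) & (j %in% gdt$idx)]
  }
  tab <- enumerate_locus_pairs(grid)
  ri <- match(tab$i, gdt$idx); rj <- match(tab$j, gdt$idx)
  tab[, chrom_i := gdt$chrom[ri]]
  tab[, chrom_j := gdt$chrom[rj]]
  tab[, GD := ifelse(chrom_i == chrom_j, abs(gdt$start[ri] - gdt$start[rj]) / 1e6, NA_real_)]
  tab[, inter := chrom_i != chrom_j]
  has_sdr <- "sdr" %in% names(triples)
  jn <- triples[, .(NR = sum(count), SDR = if (has_sdr) sum(sdr) else 0), by = .(i, j)]
  tab <- merge(tab, jn, by = c("i", "j"), all.x = TRUE)
  tab[is.na(NR), NR := 0]
  tab[is.na(SDR), SDR := 0]
  f1 <- gdt$sd_frac[match(tab$i, gdt$idx)]
  f2 <- gdt$sd_frac[match(tab$j, gdt$idx)]
  if (!has_sdr) {
    tab[, SDR := NR * (1 - (1 - f1) * (1 - f2))]
  }
  tab[, NRCSD := correct_pair_count(NR, SDR, f1, f2)]
  setorder(tab, i, j)
  setattr(tab, "sdr_mode", if (has_sdr) "observed" else "estimated")
  setattr(tab, "window_length", attr(grid, "window_length"))
  setattr(tab, "class", c("pair_counts", class(tab)))
  tab[]
}
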