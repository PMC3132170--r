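# Assembly of the analysis table: one record per locus pair with counts,
# genomic distance, breakpoint-pair flag, gene-density and DNaseI covariates
# and their natural-log transforms.

#' Gene density per window
#'
#' Fraction of the window covered by the union of genic intervals.
#'
#' @param grid A `locus_grid`.
#' @param gene_bed Genic intervals (`GRanges`, 0-based data.frame, BED path).
#' @return Numeric vector in `[0, 1]` aligned with `grid` rows.
#' @export
compute_gene_density <- function(grid, gene_bed) {
  coverage_fraction(grid, gene_bed)
}

#' DNaseI sensitivity per window
#'
#' Accumulates cleavage densities reported in fixed-step sliding windows: each
#' bedGraph record contributes `value * overlap_width / step`, so a record
#' lying entirely inside one window contributes its value once per step it
#' spans.
#'
#' @param grid A `locus_grid`.
#' @param bedgraph `GRanges` with `score`, 0-based data.frame with `score`, or
#'   bedGraph path.
#' @param step Step of the source track in bp (default 20).
#' @return Non-negative numeric vector aligned with `grid` rows.
#' @export
compute_dnase_signal <- function(grid, bedgraph, step = 20) {
  gr <- if (is(bedgraph, "GRanges")) bedgraph
        else if (is.character(bedgraph) && length(bedgraph) == 1L) read_bedgraph(bedgraph)
        else {
          dt <- as.data.table(bedgraph)
          g <- dt0_to_granges(dt); g$score <- dt$score; g
        }
  stop_if_not(!is.null(gr$score), "bedGraph signal lacks a value column")
  win <- dt0_to_granges(as.data.table(grid))
  hits <- GenomicRanges::findOverlaps(win, gr)
  out <- rep(0, length(win))
  if (length(hits)) {
    w <- GenomicRanges::width(IRanges::pintersect(
      win[S4Vectors::queryHits(hits)], gr[S4Vectors::subjectHits(hits)]
    ))
    contrib <- gr$score[S4Vectors::subjectHits(hits)] * w / step
    agg <- rowsum(contrib, S4Vectors::queryHits(hits))
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

#' Flag locus pairs containing a breakpoint pair
#'
#' A locus pair (Li, Lj) is flagged iff some breakpoint pair has one member
#' assigned to Li and the other to Lj (unordered; both members in one window
#' flag the self-pair). By default a breakpoint is assigned to the window
#' containing its midpoint; `mode = "overlap"` instead flags every window
#' combination the two members overlap. Breakpoints landing on a filtered-out
#' locus drop their pair with a message.
#'
#' @param pairs `breakpoint_pairs` with member coordinates.
#' @param grid A (filtered) `locus_grid`.
#' @param mode `"midpoint"` (default) or `"overlap"`.
#' @return `data.table(i, j)` of flagged pairs, `i <= j`, unique.
#' @export
flag_breakpoint_locus_pairs <- function(pairs, grid, mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  dt <- as.data.table(pairs)
  empty <- data.table(i = integer(), j = integer())
  if (nrow(dt) == 0L) return(empty)
  gdt <- as.data.table(grid)
  if (mode == "midpoint") {
    wl <- attr(grid, "window_length")
    key <- setNames(gdt$idx, paste0(gdt$chrom, ":", floor(gdt$start / wl)))
    assign_win <- function(chrom, s, e) {
      mid <- floor((s + e) / 2)
      unname(key[paste0(chrom, ":", floor(mid / wl))])
    }
    wi <- assign_win(dt$bp1_chrom, dt$bp1_start, dt$bp1_end)
    wj <- assign_win(dt$bp2_chrom, dt$bp2_start, dt$bp2_end)
    lost <- is.na(wi) | is.na(wj)
    if (any(lost)) {
      message(sprintf("flag_breakpoint_locus_pairs: %d pair(s) dropped (member on a filtered-out locus)", sum(lost)))
    }
    out <- data.table(i = pmin(wi[!lost], wj[!lost]), j = pmax(wi[!lost], wj[!lost]))
  } else {
    win <- dt0_to_granges(gdt)
    win_of <- function(chrom, s, e) {
      q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pmin(s + 1, e), pmax(e, s + 1)))
      GenomicRanges::findOverlaps(q, win)
    }
    h1 <- win_of(dt$bp1_chrom, dt$bp1_start, dt$bp1_end)
    h2 <- win_of(dt$bp2_chrom, dt$bp2_start, dt$bp2_end)
    l1 <- split(gdt$idx[S4Vectors::subjectHits(h1)], S4Vectors::queryHits(h1))
    l2 <- split(gdt$idx[S4Vectors::subjectHits(h2)], S4Vectors::queryHits(h2))
    combos <- lapply(seq_len(nrow(dt)), function(k) {
      a <- l1[[as.character(k)]]; b <- l2[[as.character(k)]]
      if (is.null(a) || is.null(b)) return(NULL)
      CJ(i = a, j = b)
    })
    lost <- sum(vapply(combos, is.null, logical(1)))
    if (lost > 0L) message(sprintf("flag_breakpoint_locus_pairs: %d pair(s) dropped (member on a filtered-out locus)", lost))
    out <- rbindlist(combos)
    if (nrow(out) == 0L) return(empty)
    out <- out[, .(i = pmin(i, j), j = pmax(i, j))]
  }
  unique(out[order(i, j)])
}

#' Assemble the analysis pair table
#'
#' Joins per-locus covariates onto the pair-count table and adds the pair
#' covariates and natural-log transforms: `Gcov` and `DNase` are products of
#' the two per-locus values; `log_RC = log(NRCSD)`, `log_GD = log(GD)`,
#' `log_Gcov`, `log_DNase`, each `NA` where the raw value is not strictly
#' positive (rows are marked per-analysis-excluded rather than deleted; pairs
#' with a zero-density locus drop out of `Gcov` analyses this way).
#'
#' @param counts A [pair_counts_from_triples()] table (or one with the same
#'   columns).
#' @param grid The matching `locus_grid`; optional columns `gene_density` and
#'   `dnase` feed the covariates.
#' @param flags `data.table(i, j)` from [flag_breakpoint_locus_pairs()], or
#'   `NULL` for no flags.
#' @return A `pair_table` `data.table` with columns `i, j, chrom_i, chrom_j,
#'   GD, inter, NR, SDR, NRCSD, BP, g_i, g_j, Gcov, d_i, d_j, DNase, log_RC,
#'   log_GD, log_Gcov, log_DNase`.
#' @export
assemble_pair_table <- function(counts, grid, flags = NULL) {
  tab <- copy(as.data.table(counts))
  gdt <- as.data.table(grid)
  missing <- setdiff(unique(c(tab$i, tab$j)), gdt$idx)
  stop_if_not(length(missing) == 0L,
              "pair table references window(s) absent from the grid: %s",
              paste(head(missing, 10L), collapse = ", "))
  safe_log <- function(x) ifelse(is.finite(x) & x > 0, log(x), NA_real_)
  g <- if ("gene_density" %in% names(gdt)) gdt$gene_density else rep(NA_real_, nrow(gdt))
  d <- if ("dnase" %in% names(gdt)) gdt$dnase else rep(NA_real_, nrow(gdt))
  ri <- match(tab$i, gdt$idx); rj <- match(tab$j, gdt$idx)
  tab[, g_i := g[ri]]; tab[, g_j := g[rj]]
  tab[, d_i := d[ri]]; tab[, d_j := d[rj]]
  tab[, Gcov := g_i * g_j]
  tab[, DNase := d_i * d_j]
  tab[, BP := FALSE]
  if (!is.null(flags) && nrow(flags) > 0L) {
    fl <- as.data.table(flags)[, .(i = pmin(i, j), j = pmax(i, j))]
    tab[fl, BP := TRUE, on = c("i", "j")]
  }
  tab[, log_RC := safe_log(NRCSD)]
  tab[, log_GD := safe_log(GD)]
  tab[, log_Gcov := safe_log(Gcov)]
  tab[, log_DNase := safe_log(DNase)]
  setattr(tab, "window_length", attr(counts, "window_length") %||% attr(grid, "window_length"))
  setattr(tab, "class", c("pair_table", class(tab)))
  tab[]
}

#' Write per-locus track values
#'
#' @param grid A `locus_grid` (any of `gap_frac`, `sd_frac`, `gene_density`,
#'   `dnase` present are written).
#' @param path Output TSV path.
#' @export
write_locus_tracks <- function(grid, path) {
  keep <- intersect(c("idx", "chrom", "start", "end", "gap_frac", "sd_frac",
                      "gene_density", "dnase"), names(grid))
  fwrite(as.data.table(grid)[, keep, with = FALSE], path, sep = "\t")
  invisible(path)
}
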