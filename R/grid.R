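# The locus grid: fixed-size windows tiling the autosomes, with per-window
# assembly-gap and segmental-duplication fractions.

#' Build the locus grid
#'
#' Tiles each retained chromosome with non-overlapping windows of
#' `window_length` (the last window may be short) and computes the per-window
#' assembly-gap fraction. Only autosomes are retained; by default any
#' chromosome whose name (minus a `chr` prefix) is `X`, `Y`, `M` or `MT` is
#' dropped.
#'
#' @param chrom_sizes `data.table(chrom, size)`, named vector, or path to a
#'   chrom.sizes file.
#' @param window_length Window size in bp (default 1 Mb).
#' @param gap_bed Optional assembly-gap intervals (`GRanges`, 0-based
#'   data.frame, or BED path).
#' @param autosomes Optional explicit character vector of chromosomes to keep.
#'   An empty vector is an error.
#' @return A `locus_grid` `data.table(idx, chrom, start, end, gap_frac,
#'   sd_frac)` with stable 1-based `idx` and attributes `window_length` and
#'   `chrom_sizes`.
#' @export
build_locus_grid <- function(chrom_sizes, window_length = 1e6, gap_bed = NULL,
                             autosomes = NULL) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L && file.exists(chrom_sizes)) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes <- data.table(chrom = names(chrom_sizes), size = as.numeric(chrom_sizes))
  }
  cs <- as.data.table(chrom_sizes)[, .(chrom = as.character(chrom), size = as.numeric(size))]
  stop_if_not(all(cs$size > 0), "chromosome sizes must be positive")
  stop_if_not(is.numeric(window_length) && window_length > 0, "window_length must be positive")
  if (is.null(autosomes)) {
    autosomes <- cs$chrom[!grepl("^(chr)?(X|Y|M|MT)$", cs$chrom, ignore.case = TRUE)]
  }
  stop_if_not(length(autosomes) > 0, "empty autosome list")
  cs <- cs[chrom %in% autosomes]
  stop_if_not(nrow(cs) > 0, "no chromosome matches the autosome list")
  grid <- cs[, {
    starts <- seq(0, size - 1, by = window_length)
    .(start = starts, end = pmin(starts + window_length, size))
  }, by = chrom]
  grid[, idx := .I]
  setcolorder(grid, c("idx", "chrom", "start", "end"))
  grid[, gap_frac := 0]
  grid[, sd_frac := 0]
  if (!is.null(gap_bed)) {
    grid[, gap_frac := coverage_fraction(grid, gap_bed)]
  }
  setattr(grid, "window_length", window_length)
  setattr(grid, "chrom_sizes", cs)
  setattr(grid, "class", c("locus_grid", class(grid)))
  grid
}

as_intervals_gr <- function(x) {
  if (is(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1L) return(read_bed(x))
  dt0_to_granges(as.data.table(x))
}

#' Fraction of each window covered by a set of intervals
#'
#' Overlapping intervals are merged before measuring, so the result is the
#' covered fraction of the union, in `[0, 1]`.
#'
#' @param grid A `locus_grid`.
#' @param intervals `GRanges`, 0-based data.frame, or BED path.
#' @return Numeric vector aligned with `grid` rows.
#' @export
coverage_fraction <- function(grid, intervals) {
  gr <- GenomicRanges::reduce(as_intervals_gr(intervals))
  win <- dt0_to_granges(as.data.table(grid))
  hits <- GenomicRanges::findOverlaps(win, gr)
  w <- GenomicRanges::width(IRanges::pintersect(
    win[S4Vectors::queryHits(hits)], gr[S4Vectors::subjectHits(hits)]
  ))
  covered <- rep(0, length(win))
  if (length(hits)) {
    agg <- rowsum(w, S4Vectors::queryHits(hits))
    covered[as.integer(rownames(agg))] <- agg[, 1L]
  }
  covered / GenomicRanges::width(win)
}

#' Annotate per-window segmental-duplication fraction
#'
#' @param grid A `locus_grid`.
#' @param sd_bed SD intervals (`GRanges`, 0-based data.frame, or BED path).
#' @return A copy of `grid` with `sd_frac` filled.
#' @export
compute_sd_fraction <- function(grid, sd_bed) {
  out <- copy(grid)
  out[, sd_frac := coverage_fraction(out, sd_bed)]
  out
}

#' Drop windows dominated by assembly gaps
#'
#' Windows with gap fraction strictly greater than `max_gap_fraction` are
#' removed ("more than 50 percent covered by N's"); a window at exactly the
#' threshold is retained. Window indices are stable: remaining rows keep the
#' `idx` they had before filtering, so count-triple bin indices stay valid.
#'
#' @param grid A `locus_grid`.
#' @param max_gap_fraction Strict threshold (default 0.5).
#' @return The filtered `locus_grid`.
#' @export
filter_loci <- function(grid, max_gap_fraction = 0.5) {
  out <- grid[gap_frac <= max_gap_fraction]
  setattr(out, "window_length", attr(grid, "window_length"))
  setattr(out, "chrom_sizes", attr(grid, "chrom_sizes"))
  setattr(out, "class", unique(c("locus_grid", class(out))))
  out
}
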