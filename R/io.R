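# Readers and writers for the plain-text interchange formats used throughout:
# synteny-block tables (TSV), BED / bedGraph (via rtracklayer, so the native
# 0-based half-open BED convention is converted at the boundary), chrom.sizes,
# and sparse count triples with a companion bin BED. All in-memory coordinates
# are 0-based half-open.

BLOCK_TABLE_COLS <- c(
  "block_id", "chromA", "startA", "endA", "strandA",
  "chromB", "startB", "endB", "strandB"
)

#' Read a synteny block table
#'
#' A block table has one row per orthologous synteny block with its coordinates
#' and orientation on the two genomes being compared. Columns:
#' `block_id, chromA, startA, endA, strandA, chromB, startB, endB, strandB`
#' (0-based half-open, strand `+`/`-`).
#'
#' @param path Path to a tab-separated block table with header.
#' @return A `data.table` with the nine block-table columns.
#' @export
read_block_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  missing <- setdiff(BLOCK_TABLE_COLS, names(dt))
  stop_if_not(length(missing) == 0L,
              "block table %s lacks column(s): %s", path, paste(missing, collapse = ", "))
  dt[, BLOCK_TABLE_COLS, with = FALSE]
}

#' Write a synteny block table
#'
#' @param blocks A `data.table` with the block-table columns, or a list of two
#'   [block_order()] objects named `A` and `B` sharing block ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_block_table <- function(blocks, path) {
  if (is.list(blocks) && !is.data.frame(blocks) && all(c("A", "B") %in% names(blocks))) {
    blocks <- block_table_from_orders(blocks$A, blocks$B)
  }
  fwrite(as.data.table(blocks)[, BLOCK_TABLE_COLS, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' Combine two per-genome block orders into one block table
#'
#' @param orderA,orderB [block_order()] objects over the same block ids.
#' @return A `data.table` in block-table layout.
#' @export
block_table_from_orders <- function(orderA, orderB) {
  a <- as.data.table(orderA)[, .(block_id, chromA = chrom, startA = start, endA = end, strandA = strand)]
  b <- as.data.table(orderB)[, .(block_id, chromB = chrom, startB = start, endB = end, strandB = strand)]
  out <- merge(a, b, by = "block_id", all = FALSE)
  stop_if_not(nrow(out) == nrow(a) && nrow(out) == nrow(b),
              "block ids differ between the two orders")
  setorder(out, chromA, startA)
  out[]
}

#' Split a block table into its two per-genome orders
#'
#' @param blocks Block table (`data.table` or path).
#' @return A list with [block_order()] objects `A` and `B`.
#' @export
block_orders_from_table <- function(blocks) {
  if (is.character(blocks)) blocks <- read_block_table(blocks)
  blocks <- as.data.table(blocks)
  list(
    A = block_order(blocks[, .(block_id, chrom = chromA, start = startA, end = endA, strand = strandA)]),
    B = block_order(blocks[, .(block_id, chrom = chromB, start = startB, end = endB, strand = strandB)])
  )
}

#' Read a chrom.sizes file
#'
#' @param path Two-column whitespace-separated file: chromosome name, length.
#' @return `data.table` with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, col.names = c("chrom", "size"))
  stop_if_not(all(dt$size > 0), "non-positive chromosome size in %s", path)
  dt
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes `data.table(chrom, size)`.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  fwrite(as.data.table(chrom_sizes)[, .(chrom, size)], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read intervals from a BED file
#'
#' @param path BED path (>= 3 columns).
#' @return A `GRanges` (rtracklayer converts BED's 0-based half-open records).
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write intervals to a BED file
#'
#' @param x A `GRanges`, or a data.frame with 0-based half-open
#'   `chrom`/`start`/`end` (optional `name`, `score`).
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  if (!is(x, "GRanges")) {
    dt <- as.data.table(x)
    gr <- dt0_to_granges(dt)
    if (!is.null(dt$name)) gr$name <- as.character(dt$name)
    if (!is.null(dt$score)) gr$score <- dt$score
    x <- gr
  }
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph path (chrom, start, end, value).
#' @return A `GRanges` with a numeric `score` column.
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' @rdname read_bedgraph
#' @param x `GRanges` with `score`, or data.frame with 0-based
#'   `chrom`/`start`/`end`/`score`.
#' @export
write_bedgraph <- function(x, path) {
  if (!is(x, "GRanges")) {
    dt <- as.data.table(x)
    gr <- dt0_to_granges(dt)
    gr$score <- dt$score
    x <- gr
  }
  rtracklayer::export(x, path, format = "bedGraph")
  invisible(path)
}

#' Read sparse Hi-C count triples
#'
#' Triples are tab-separated `bin_i, bin_j, count` with 0-based bin indices,
#' `bin_i <= bin_j`, plus an optional fourth `sdr` column counting reads with
#' at least one end inside a segmental duplication. Indices refer to the
#' companion bin BED ([read_bin_bed()]).
#'
#' @param path Triples path.
#' @return `data.table` with 1-based columns `i`, `j`, `count` (and `sdr` if
#'   present in the file).
#' @export
read_count_triples <- function(path) {
  dt <- fread(path, header = TRUE)
  stop_if_not(all(c("bin_i", "bin_j", "count") %in% names(dt)),
              "triples file %s must have columns bin_i, bin_j, count", path)
  stop_if_not(all(dt$bin_i <= dt$bin_j), "triples file %s has bin_i > bin_j", path)
  stop_if_not(all(dt$count >= 0 & dt$count == floor(dt$count)),
              "triples file %s has non-integer or negative counts", path)
  out <- data.table(i = dt$bin_i + 1L, j = dt$bin_j + 1L, count = as.numeric(dt$count))
  if ("sdr" %in% names(dt)) out[, sdr := as.numeric(dt$sdr)]
  out
}

#' @rdname read_count_triples
#' @param triples `data.table(i, j, count[, sdr])` with 1-based indices.
#' @export
write_count_triples <- function(triples, path) {
  dt <- as.data.table(triples)
  out <- data.table(bin_i = dt$i - 1L, bin_j = dt$j - 1L, count = dt$count)
  if (!is.null(dt$sdr)) out[, sdr := dt$sdr]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a companion bin BED mapping bin indices to windows
#'
#' The bin BED's `name` column carries the 0-based bin index.
#'
#' @param path Bin BED path.
#' @return `data.table(idx, chrom, start, end)` with 1-based `idx`.
#' @export
read_bin_bed <- function(path) {
  gr <- read_bed(path)
  dt <- granges_to_dt0(gr)
  nm <- gr$name
  stop_if_not(!is.null(nm) && !anyNA(suppressWarnings(as.integer(nm))),
              "bin BED %s must carry the 0-based bin index in the name column", path)
  dt[, idx := as.integer(nm) + 1L]
  setcolorder(dt, c("idx", "chrom", "start", "end"))
  setorder(dt, idx)
  dt[]
}

#' @rdname read_bin_bed
#' @param grid A [build_locus_grid()] object (its `idx` is written 0-based).
#' @export
write_bin_bed <- function(grid, path) {
  dt <- as.data.table(grid)[, .(chrom, start, end, name = idx - 1L)]
  write_bed(dt, path)
}
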