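# Fixture bundles: self-describing on-disk datasets (block tables, covariate
# BEDs, DNase bedGraph, bin BED + count triples, ground-truth manifest) that
# round-trip through the pipeline readers.

#' Generate a complete ground-truthed fixture
#'
#' Simulates a rearrangement scenario, builds a 1-Mb locus grid over the
#' resulting genome (plus an optional breakpoint-free extra chromosome that
#' provides inter-chromosomal pairs), simulates covariate tracks and contact
#' counts, and optionally applies the SD multi-mapping bias.
#'
#' @param scenario_cfg A [scenario_config()].
#' @param contact_cfg A [contact_config()].
#' @param track_cfg A [track_config()].
#' @param out_dir Directory to write the bundle to (`NULL` keeps everything in
#'   memory).
#' @param window_length Grid window in bp (default 1 Mb).
#' @param extra_chrom_mb Length (Mb) of an extra breakpoint-free chromosome
#'   (`0` for none; default 50).
#' @param n_gap_windows Number of non-breakpoint windows buried under assembly
#'   gaps (default 2).
#' @param bias_rate SD relocation rate (`0` disables the bias simulation).
#' @param n_sd_families With bias: number of 2-window SD families built from
#'   the highest-SD windows (breakpoint windows preferred).
#' @return List with `scenario`, `grid`, `tracks`, `flags`, `triples`,
#'   `families`, `bp_windows`, and (when written) `paths`.
#' @export
generate_fixture <- function(scenario_cfg = scenario_config(),
                             contact_cfg = contact_config(),
                             track_cfg = track_config(),
                             out_dir = NULL, window_length = 1e6,
                             extra_chrom_mb = 50, n_gap_windows = 2,
                             bias_rate = 0, n_sd_families = 2) {
  scen <- simulate_rearrangement_scenario(scenario_cfg)
  sizes <- data.table(chrom = "chr1", size = genome_length(scen$config))
  if (extra_chrom_mb > 0) {
    sizes <- rbind(sizes, data.table(chrom = "chr2", size = extra_chrom_mb * 1e6))
  }
  grid <- build_locus_grid(sizes, window_length)
  flags <- flag_breakpoint_locus_pairs(scen$truth_pairs, grid)
  bp_windows <- unique(c(flags$i, flags$j))
  gap_windows <- integer(0)
  if (n_gap_windows > 0) {
    candidates <- setdiff(as.data.table(grid)$idx, bp_windows)
    gap_windows <- with_seed(scenario_cfg$seed + 1L,
                             sample(candidates, min(n_gap_windows, length(candidates))))
  }
  tracks <- simulate_covariate_tracks(grid, bp_windows, track_cfg, gap_windows)
  triples <- simulate_contact_counts(grid, flags, contact_cfg)
  families <- list()
  if (bias_rate > 0 && n_sd_families > 0) {
    ord <- tracks[order(-sd_frac)]
    pref <- c(intersect(ord$idx, bp_windows), setdiff(ord$idx, bp_windows))
    n_fam <- min(n_sd_families, length(pref) %/% 2L)
    top <- head(pref, 2L * n_fam)
    families <- split(top, rep(seq_len(n_fam), each = 2L))
    sdv <- rep(0, max(tracks$idx)); sdv[tracks$idx] <- tracks$sd_frac
    triples <- simulate_sd_mapping_bias(triples, sdv, families, bias_rate,
                                        seed = scenario_cfg$seed + 2L)
  }
  out <- list(scenario = scen, grid = grid, tracks = tracks, flags = flags,
              triples = triples, families = families, bp_windows = bp_windows)
  if (!is.null(out_dir)) out$paths <- write_fixture_bundle(out, out_dir)
  out
}

frac_to_bed <- function(grid, frac, path) {
  gdt <- as.data.table(grid)
  len <- round(frac * (gdt$end - gdt$start))
  keep <- len > 0
  write_bed(data.table(chrom = gdt$chrom[keep], start = gdt$start[keep],
                       end = gdt$start[keep] + len[keep]), path)
}

#' Write a fixture bundle to disk
#'
#' Emits block tables for the three genome comparisons, SD/gene/gap BEDs and a
#' DNase bedGraph (per-window values encoded as intervals so the pipeline
#' readers recover them), the bin BED and count triples, the ground-truth pair
#' table, chrom.sizes and a JSON manifest.
#'
#' @param fixture A [generate_fixture()] result (or compatible list).
#' @param out_dir Output directory (created if needed).
#' @param dnase_step Step encoded in the bedGraph (default 20).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture_bundle <- function(fixture, out_dir, dnase_step = 20) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stop_if_not(dir.exists(out_dir), "cannot create output directory %s", out_dir)
  p <- function(f) file.path(out_dir, f)
  scen <- fixture$scenario
  grid <- fixture$grid
  tracks <- as.data.table(fixture$tracks)
  gdt <- as.data.table(grid)
  stopifnot(identical(tracks$idx, gdt$idx))
  paths <- list(
    blocks_hm = p("blocks_human_mouse.tsv"),
    blocks_ho = p("blocks_human_outgroup.tsv"),
    blocks_mo = p("blocks_mouse_outgroup.tsv"),
    chrom_sizes = p("chrom.sizes"),
    sd = p("sd.bed"), genes = p("genes.bed"), gaps = p("gaps.bed"),
    dnase = p("dnase.bedGraph"),
    bins = p("bins.bed"), triples = p("counts.tsv"),
    truth_pairs = p("truth_pairs.tsv"),
    manifest = p("manifest.json")
  )
  write_block_table(list(A = scen$orders$human, B = scen$orders$mouse), paths$blocks_hm)
  write_block_table(list(A = scen$orders$human, B = scen$orders$outgroup), paths$blocks_ho)
  write_block_table(list(A = scen$orders$mouse, B = scen$orders$outgroup), paths$blocks_mo)
  write_chrom_sizes(attr(grid, "chrom_sizes"), paths$chrom_sizes)
  frac_to_bed(grid, tracks$sd_frac, paths$sd)
  frac_to_bed(grid, tracks$gene_density, paths$genes)
  frac_to_bed(grid, tracks$gap_frac, paths$gaps)
  wdt <- data.table(chrom = gdt$chrom, start = gdt$start, end = gdt$end,
                    score = tracks$dnase * dnase_step / (gdt$end - gdt$start))
  write_bedgraph(wdt, paths$dnase)
  write_bin_bed(grid, paths$bins)
  write_count_triples(fixture$triples, paths$triples)
  fwrite(scen$truth_pairs, paths$truth_pairs, sep = "\t")
  manifest <- list(
    package_version = as.character(packageVersion("spatialsynteny")),
    scenario_config = unclass(scen$config),
    n_truth_pairs = nrow(scen$truth_pairs),
    n_reciprocal = sum(scen$truth_pairs$reciprocal),
    n_flagged_locus_pairs = nrow(fixture$flags),
    n_windows = nrow(gdt),
    n_triples = nrow(fixture$triples),
    total_reads = sum(fixture$triples$count),
    sd_families = fixture$families,
    dnase_step = dnase_step
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Read a fixture bundle back from disk
#'
#' @param dir Bundle directory written by [write_fixture_bundle()].
#' @return List with `orders_hm`, `orders_ho`, `orders_mo`, `chrom_sizes`,
#'   `bins`, `triples`, `truth_pairs`, `manifest` and the track paths.
#' @export
read_fixture_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(
    orders_hm = block_orders_from_table(p("blocks_human_mouse.tsv")),
    orders_ho = block_orders_from_table(p("blocks_human_outgroup.tsv")),
    orders_mo = block_orders_from_table(p("blocks_mouse_outgroup.tsv")),
    chrom_sizes = read_chrom_sizes(p("chrom.sizes")),
    bins = read_bin_bed(p("bins.bed")),
    triples = read_count_triples(p("counts.tsv")),
    truth_pairs = fread(p("truth_pairs.tsv")),
    manifest = jsonlite::read_json(p("manifest.json")),
    paths = list(sd = p("sd.bed"), genes = p("genes.bed"), gaps = p("gaps.bed"),
                 dnase = p("dnase.bedGraph"), chrom_sizes = p("chrom.sizes"),
                 blocks_hm = p("blocks_human_mouse.tsv"),
                 blocks_ho = p("blocks_human_outgroup.tsv"),
                 blocks_mo = p("blocks_mouse_outgroup.tsv"),
                 bins = p("bins.bed"), triples = p("counts.tsv"))
  )
}
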