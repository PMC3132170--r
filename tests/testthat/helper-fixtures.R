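# Shared builders for programmatic fixtures: everything is generated in code
# at test time.

library(data.table)

# compact scenario config for permutation-level tests
tiny_cfg <- function(n, seed = 1) {
  scenario_config(n_blocks = n, block_length = 1e6, spacer = 1e5,
                  n_inversions_A = 0, n_translocations_A = 0,
                  n_inversions_B = 0, n_translocations_B = 0, seed = seed)
}

# run the coordinate-based module on explicit permutations and return pairs
# in a canonical comparable form
module_pairs_canonical <- function(cfg, pa, pb, po = NULL) {
  sc <- spatialsynteny:::build_scenario(cfg, pa, pb, po %||% seq_along(pa))
  hd <- md <- NULL
  if (!is.null(po)) {
    hd <- as.data.table(find_breakpoints(sc$orders$human, sc$orders$outgroup,
                                         include_telomeres = FALSE))[, .(chrom, start, end)]
    md <- as.data.table(find_breakpoints(sc$orders$mouse, sc$orders$outgroup,
                                         include_telomeres = FALSE))[, .(chrom, start, end)]
  }
  pr <- call_breakpoint_pairs(list(A = sc$orders$human, B = sc$orders$mouse), hd, md)
  out <- as.data.table(pr)[, .(bp1_start, bp1_end, bp2_start, bp2_end, n_links,
                               reciprocal, origin)]
  setorder(out, bp1_start, bp2_start)
  list(scenario = sc, pairs = as.data.frame(out))
}

truth_pairs_canonical <- function(sc) {
  out <- copy(sc$truth_pairs)[, .(bp1_start, bp1_end, bp2_start, bp2_end,
                                  n_links, reciprocal, origin)]
  setorder(out, bp1_start, bp2_start)
  as.data.frame(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-chromosome pair table with randomly flagged pairs, used by the
# association and acceptance tests
sim_pair_table <- function(n_windows, n_flags, ccfg, flag_seed) {
  grid <- build_locus_grid(data.table(chrom = "chr1", size = n_windows * 1e6), 1e6)
  ep <- enumerate_locus_pairs(grid)
  ep <- ep[i < j]
  flags <- spatialsynteny:::with_seed(flag_seed, ep[sample(.N, n_flags)])
  triples <- simulate_contact_counts(grid, flags, ccfg)
  assemble_pair_table(pair_counts_from_triples(triples, grid), grid, flags)
}

# small end-to-end fixture (fast): ~12 blocks of 3 Mb + 20 Mb extra chromosome
small_fixture <- function(out_dir = NULL, seed = 7, bias_rate = 0, ...) {
  generate_fixture(
    scenario_config(n_blocks = 12, block_length = 3e6, spacer = 2e5, seed = seed),
    contact_config(seed = seed), track_config(seed = seed),
    out_dir = out_dir, extra_chrom_mb = 20, bias_rate = bias_rate, ...
  )
}

# all distinct single events on an identity permutation of size n
all_single_events <- function(n) {
  evs <- list()
  for (i in seq_len(n)) for (j in i:n) {
    evs[[length(evs) + 1L]] <- spatialsynteny:::invert_segment(seq_len(n), i, j)
  }
  for (p in seq_len(n)) for (g in 0:(n - 1L)) {
    if (g == p - 1L) next
    evs[[length(evs) + 1L]] <- spatialsynteny:::translocate_block(seq_len(n), p, g)
  }
  evs
}
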