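# End-to-end orchestration: configuration, input validation, and the staged
# pipeline (breakpoints -> pairing -> origins; grid -> binning -> correction;
# table assembly; association tests) with a reproducibility manifest.

#' Build a pipeline configuration
#'
#' @param blocks_hm Block table for the focal genome comparison (human vs
#'   mouse). Required.
#' @param triples,bins Count triples and companion bin BED. Required.
#' @param chrom_sizes chrom.sizes for the focal (human) genome. Required.
#' @param blocks_ho,blocks_mo Optional outgroup block tables (human vs
#'   outgroup, mouse vs outgroup); both needed for origin assignment.
#' @param sd,genes,gaps,dnase Optional SD BED, gene BED, assembly-gap BED and
#'   DNaseI bedGraph; analyses needing a missing track are skipped with a
#'   notice.
#' @param out_dir Output directory. Required for [run_pipeline()].
#' @param window_length Grid window (default 1 Mb).
#' @param gap_threshold Strict gap-fraction filter (default 0.5).
#' @param B Resampling replicates (default 500).
#' @param seed Integer master seed.
#' @param include_telomeres Emit telomere sentinel breakpoints (default TRUE).
#' @param bp_mode Breakpoint-to-window assignment (`"midpoint"`/`"overlap"`).
#' @param dnase_step bedGraph step (default 20).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(blocks_hm, triples, bins, chrom_sizes,
                            blocks_ho = NULL, blocks_mo = NULL,
                            sd = NULL, genes = NULL, gaps = NULL, dnase = NULL,
                            out_dir = NULL, window_length = 1e6,
                            gap_threshold = 0.5, B = 500, seed = 1,
                            include_telomeres = TRUE,
                            bp_mode = "midpoint", dnase_step = 20) {
  cfg <- list(blocks_hm = blocks_hm, triples = triples, bins = bins,
              chrom_sizes = chrom_sizes, blocks_ho = blocks_ho,
              blocks_mo = blocks_mo, sd = sd, genes = genes, gaps = gaps,
              dnase = dnase, out_dir = out_dir, window_length = window_length,
              gap_threshold = gap_threshold, B = B, seed = seed,
              include_telomeres = include_telomeres, bp_mode = bp_mode,
              dnase_step = dnase_step)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize / restore a pipeline configuration (JSON)
#'
#' @param cfg A [pipeline_config()].
#' @param path JSON path.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path)
  x <- lapply(x, function(v) if (is.list(v) && length(v) == 0L) NULL else v)
  do.call(pipeline_config, x)
}

#' Validate pipeline input files
#'
#' Checks existence and well-formedness of every referenced file: BED and
#' bedGraph structure, coordinate sanity, bin-index consistency between the
#' triples and the bin BED, and the block-id bijection between the two
#' genomes of each block table. Returns diagnostics instead of raising.
#'
#' @param cfg A [pipeline_config()] (paths are taken from it).
#' @return `data.table(file, check, message)`; zero rows means all checks
#'   passed.
#' @export
validate_inputs <- function(cfg) {
  diags <- list()
  note <- function(file, check, msg) {
    diags[[length(diags) + 1L]] <<- data.table(file = file, check = check, message = msg)
  }
  try_check <- function(file, check, expr) {
    tryCatch(expr, error = function(e) note(file, check, conditionMessage(e)))
  }
  paths <- cfg[c("blocks_hm", "blocks_ho", "blocks_mo", "triples", "bins",
                 "chrom_sizes", "sd", "genes", "gaps", "dnase")]
  for (nm in names(paths)) {
    pth <- paths[[nm]]
    if (is.null(pth)) next
    if (!file.exists(pth)) { note(pth, "exists", sprintf("input '%s' not found", nm)); next }
    if (nm %in% c("blocks_hm", "blocks_ho", "blocks_mo")) {
      try_check(pth, "block_table", {
        tb <- read_block_table(pth)
        dupA <- tb$block_id[duplicated(tb$block_id)]
        if (length(dupA)) note(pth, "block_table", sprintf("duplicated block id(s): %s", paste(unique(dupA), collapse = ",")))
        if (any(tb$startA >= tb$endA) || any(tb$startB >= tb$endB))
          note(pth, "block_table", "block with start >= end")
        invisible(NULL)
      })
    } else if (nm == "chrom_sizes") {
      try_check(pth, "chrom_sizes", { read_chrom_sizes(pth); invisible(NULL) })
    } else if (nm == "dnase") {
      try_check(pth, "bedgraph", {
        gr <- read_bedgraph(pth)
        if (is.null(gr$score)) note(pth, "bedgraph", "no value column")
        invisible(NULL)
      })
    } else if (nm %in% c("sd", "genes", "gaps", "bins")) {
      try_check(pth, "bed", { read_bed(pth); invisible(NULL) })
    }
  }
  if (!is.null(cfg$triples) && file.exists(cfg$triples) &&
      !is.null(cfg$bins) && file.exists(cfg$bins)) {
    try_check(cfg$triples, "bin_index", {
      tr <- read_count_triples(cfg$triples)
      bins <- read_bin_bed(cfg$bins)
      bad <- which(!(tr$i %in% bins$idx) | !(tr$j %in% bins$idx))
      if (length(bad)) {
        note(cfg$triples, "bin_index",
             sprintf("triple line(s) %s reference bin indices missing from the bin BED",
                     paste(head(bad, 5L), collapse = ",")))
      }
      invisible(NULL)
    })
  }
  if (length(diags) == 0L) {
    return(data.table(file = character(), check = character(), message = character()))
  }
  rbindlist(diags)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes breakpoint detection/pairing/origin assignment, grid construction
#' and filtering, count binning and SD correction, analysis-table assembly,
#' the nested ANCOVA comparisons, the inter-chromosomal rank-sum test and the
#' stratified resampling tests, and writes all result tables plus a
#' reproducibility manifest to `cfg$out_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with `pairs`, `grid`, `table`, `fits`,
#'   `comparisons`, `ranksum`, `resampling`, `manifest`, `paths`.
#' @export
run_pipeline <- function(cfg) {
  stop_if_not(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  stop_if_not(!is.null(cfg$out_dir), "cfg$out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  log_counts <- list()

  pairs <- stage("breakpoints", {
    orders <- block_orders_from_table(cfg$blocks_hm)
    og_A <- og_B <- NULL
    if (!is.null(cfg$blocks_ho) && !is.null(cfg$blocks_mo)) {
      oho <- block_orders_from_table(cfg$blocks_ho)
      omo <- block_orders_from_table(cfg$blocks_mo)
      og_A <- as.data.table(find_breakpoints(oho$A, oho$B, include_telomeres = FALSE,
                                             genome = "HO"))[, .(chrom, start, end)]
      og_B <- as.data.table(find_breakpoints(omo$A, omo$B, include_telomeres = FALSE,
                                             genome = "MO"))[, .(chrom, start, end)]
    } else if (!is.null(cfg$blocks_ho) || !is.null(cfg$blocks_mo)) {
      message("run_pipeline: only one outgroup block table supplied; origins not assigned")
    }
    call_breakpoint_pairs(orders, og_A, og_B, include_telomeres = cfg$include_telomeres)
  })
  log_counts$breakpoint_pairs <- nrow(pairs)
  log_counts$reciprocal_pairs <- sum(pairs$reciprocal)

  grid <- stage("grid", {
    g <- build_locus_grid(cfg$chrom_sizes, cfg$window_length, gap_bed = cfg$gaps)
    log_counts$windows_total <- nrow(g)
    g <- filter_loci(g, cfg$gap_threshold)
    log_counts$windows_retained <- nrow(g)
    if (!is.null(cfg$sd)) g <- compute_sd_fraction(g, cfg$sd)
    if (!is.null(cfg$genes)) g[, gene_density := compute_gene_density(g, cfg$genes)]
    if (is.null(cfg$dnase)) {
      message("run_pipeline: no DNase track; DNase analyses skipped")
    } else {
      g[, dnase := compute_dnase_signal(g, cfg$dnase, step = cfg$dnase_step)]
    }
    g
  })

  table <- stage("pair_table", {
    triples <- read_count_triples(cfg$triples)
    bins <- read_bin_bed(cfg$bins)
    # map bin indices onto grid indices by window identity
    m <- match(sprintf("%s:%.0f", bins$chrom, bins$start),
               sprintf("%s:%.0f", grid$chrom, grid$start))
    remap <- function(v) m[match(v, bins$idx)]
    triples[, `:=`(i = remap(i), j = remap(j))]
    dropped <- triples[is.na(i) | is.na(j)]
    if (nrow(dropped)) {
      message(sprintf("run_pipeline: %d triple(s) on filtered-out bins dropped", nrow(dropped)))
      triples <- triples[!is.na(i) & !is.na(j)]
    }
    triples[, `:=`(i2 = pmin(i, j), j2 = pmax(i, j))]
    triples[, `:=`(i = i2, j = j2, i2 = NULL, j2 = NULL)]
    counts <- pair_counts_from_triples(triples, grid)
    log_counts$locus_pairs <- nrow(counts)
    flags <- flag_breakpoint_locus_pairs(pairs, grid, mode = cfg$bp_mode)
    log_counts$flagged_locus_pairs <- nrow(flags)
    assemble_pair_table(counts, grid, flags)
  })

  specs <- ancova_models()
  fits <- list(); comparisons <- list(); resampling <- list(); rs <- NULL
  stage("association", {
    have_flag <- any(table$BP & !table$inter & !is.na(table$GD) & table$GD >= 1)
    if (!have_flag) {
      message("run_pipeline: no flagged intra-chromosomal pair; model fits skipped")
    } else {
      run_cmp <- function(id, s, b) {
        cmp <- compare_models(table, specs[[s]], specs[[b]])
        fits[[s]] <<- cmp$small; fits[[b]] <<- cmp$big
        comparisons[[id]] <<- cmp$test
      }
      run_cmp("M1_vs_M0", "M0", "M1")
      run_cmp("M2_vs_M1", "M1", "M2")
      if (!is.null(cfg$genes)) {
        run_cmp("M4_vs_M3", "M3", "M4")
        run_cmp("M5_vs_M4", "M4", "M5")
      }
      if (!is.null(cfg$dnase)) {
        run_cmp("M7_vs_M6", "M6", "M7")
        run_cmp("M8_vs_M7", "M7", "M8")
      }
      schemes <- list(distance = stratum_scheme())
      if (!is.null(cfg$genes)) schemes$distance_gene <- stratum_scheme(gene = TRUE)
      if (!is.null(cfg$dnase)) schemes$distance_dnase <- stratum_scheme(dnase = TRUE)
      for (k in seq_along(schemes)) {
        resampling[[names(schemes)[k]]] <- stratified_resampling_test(
          table, schemes[[k]], B = cfg$B, seed = cfg$seed + k)
      }
    }
    inter_f <- table[inter == TRUE & BP == TRUE & !is.na(NRCSD), NRCSD]
    inter_u <- table[inter == TRUE & BP == FALSE & !is.na(NRCSD), NRCSD]
    if (length(inter_f) > 0 && length(inter_u) > 0) {
      rs <- ranksum_test(inter_f, inter_u)
    } else {
      message("run_pipeline: no inter-chromosomal flagged/unflagged split; rank-sum skipped")
    }
  })

  paths <- stage("outputs", {
    write_pair_table(pairs, p("breakpoint_pairs.tsv"))
    write_locus_tracks(grid, p("loci.tsv"))
    fwrite(table, p("analysis_table.tsv"), sep = "\t")
    res <- rbindlist(lapply(names(comparisons), function(id) {
      cmp <- comparisons[[id]]
      data.table(test = id, statistic = cmp$f, df1 = cmp$df1, df2 = cmp$df2, p = cmp$p)
    }))
    if (!is.null(rs)) {
      res <- rbind(res, data.table(test = "ranksum_inter", statistic = rs$statistic,
                                   df1 = NA_integer_, df2 = NA_integer_, p = rs$p))
    }
    for (nm in names(resampling)) {
      r <- resampling[[nm]]
      res <- rbind(res, data.table(test = paste0("resampling_", nm),
                                   statistic = r$observed, df1 = r$B,
                                   df2 = NA_integer_, p = r$p))
    }
    fwrite(res, p("results.tsv"), sep = "\t")
    report <- c(
      "spatialsynteny pipeline report",
      sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      "",
      sprintf("breakpoint pairs: %d (%d reciprocal)", log_counts$breakpoint_pairs,
              log_counts$reciprocal_pairs),
      sprintf("windows: %d retained of %d", log_counts$windows_retained,
              log_counts$windows_total),
      sprintf("locus pairs: %d (%d flagged)", log_counts$locus_pairs,
              log_counts$flagged_locus_pairs),
      "",
      if (nrow(res)) capture_table(res) else "no tests run"
    )
    writeLines(report, p("report.txt"))
    manifest <- list(
      package_version = as.character(packageVersion("spatialsynteny")),
      r_version = R.version.string,
      config = unclass(cfg),
      counts = log_counts,
      sdr_mode = attr(table, "sdr_mode") %||% "unknown"
    )
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, null = "null", digits = NA)
    list(breakpoint_pairs = p("breakpoint_pairs.tsv"), loci = p("loci.tsv"),
         analysis_table = p("analysis_table.tsv"), results = p("results.tsv"),
         report = p("report.txt"), manifest = p("manifest.json"))
  })

  invisible(list(pairs = pairs, grid = grid, table = table, fits = fits,
                 comparisons = comparisons, ranksum = rs,
                 resampling = resampling, manifest = log_counts, paths = paths))
}

capture_table <- function(dt) paste(utils::capture.output(print(dt)), collapse = "\n")
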