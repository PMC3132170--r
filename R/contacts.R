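# Simulation of Hi-C locus-pair counts with log-log distance decay plus an
# additive breakpoint effect, of covariate tracks (SD fraction, gene density,
# DNaseI signal, assembly gaps), and of the segmental-duplication
# multi-mapping bias that relocates read ends between SD copies.

#' Configuration of the contact-count generator
#'
#' Intra-chromosomal pairs at distance GD (Mb) follow
#' `count = round(exp(mu + a*log(GD) + BP*(b + c*log(GD)) + N(0, sigma)))`
#' (natural logs). Defaults are the printed M2-style estimates of the
#' distance-decay analysis: intercept ~6, slope ~-0.8, breakpoint main effect
#' 0.728, breakpoint-distance interaction -0.254. Inter-chromosomal pairs are
#' Poisson with mean `inter_mean` (5 reads on average per locus pair).
#'
#' @param mu Intercept on the natural-log scale.
#' @param a Distance slope.
#' @param b Breakpoint main effect.
#' @param c Breakpoint x log-distance interaction.
#' @param sigma Residual standard deviation on the log scale (>= 0).
#' @param inter_mean Mean count of inter-chromosomal pairs.
#' @param self_gd_mb Effective distance (Mb) at which the decay model is
#'   evaluated for self-pairs, emulating the dominant Hi-C diagonal; self-pair
#'   counts are retained in the table but excluded downstream from every
#'   log-distance analysis. `0` leaves self-pairs empty.
#' @param seed Integer seed.
#' @return A `contact_config` list.
#' @export
contact_config <- function(mu = 6.0, a = -0.8, b = 0.728, c = -0.254,
                           sigma = 0.5, inter_mean = 5, self_gd_mb = 0.5,
                           seed = 1) {
  stop_if_not(sigma >= 0, "sigma must be >= 0")
  stop_if_not(inter_mean >= 0, "inter_mean must be >= 0")
  stop_if_not(self_gd_mb >= 0, "self_gd_mb must be >= 0")
  structure(list(mu = mu, a = a, b = b, c = c, sigma = sigma,
                 inter_mean = inter_mean, self_gd_mb = self_gd_mb, seed = seed),
            class = "contact_config")
}

#' Simulate sparse contact-count triples over a locus grid
#'
#' Every intra-chromosomal pair at `GD >= 1` Mb gets a log-linear count with
#' Gaussian noise; inter-chromosomal pairs get Poisson counts; self-pairs are
#' left at zero. Deterministic given `cfg$seed`.
#'
#' @param grid A `locus_grid`.
#' @param bp_flags `data.table(i, j)` of flagged (breakpoint-containing) locus
#'   pairs, or `NULL`.
#' @param cfg A [contact_config()].
#' @param pairs Optional explicit `data.table(i, j)` of pairs to simulate
#'   (defaults to all pairs over the grid); an explicit intra-chromosomal pair
#'   at `GD <= 0` is rejected.
#' @return Sparse `data.table(i, j, count)` (rows with positive counts only);
#'   attribute `expected` holds the full table with the noiseless expected
#'   log-count (`NA` for inter/self pairs).
#' @export
simulate_contact_counts <- function(grid, bp_flags, cfg, pairs = NULL) {
  stop_if_not(inherits(cfg, "contact_config"), "cfg must be a contact_config")
  explicit <- !is.null(pairs)
  if (is.null(pairs)) pairs <- enumerate_locus_pairs(grid)
  tab <- as.data.table(pairs)[, .(i, j)]
  tab[, GD := compute_genomic_distance(grid, i, j)]
  tab[, inter := is.na(GD)]
  if (explicit) {
    stop_if_not(!any(!tab$inter & tab$GD <= 0),
                "explicit intra-chromosomal pair with GD <= 0")
  }
  tab[, BP := FALSE]
  if (!is.null(bp_flags) && nrow(bp_flags) > 0L) {
    fl <- as.data.table(bp_flags)[, .(i = pmin(i, j), j = pmax(i, j))]
    tab[fl, BP := TRUE, on = c("i", "j")]
  }
  with_seed(cfg$seed, {
    tab[, count := 0]
    tab[, mu_log := NA_real_]
    intra <- which(!tab$inter & tab$GD >= 1)
    lgd <- log(tab$GD[intra])
    m <- cfg$mu + cfg$a * lgd + as.numeric(tab$BP[intra]) * (cfg$b + cfg$c * lgd)
    tab[intra, mu_log := m]
    tab[intra, count := round(exp(m + rnorm(length(intra), 0, cfg$sigma)))]
    if (cfg$self_gd_mb > 0) {
      selfs <- which(!tab$inter & tab$GD == 0)
      m0 <- cfg$mu + cfg$a * log(cfg$self_gd_mb)
      tab[selfs, count := round(exp(m0 + rnorm(length(selfs), 0, cfg$sigma)))]
    }
    inter_rows <- which(tab$inter)
    tab[inter_rows, count := as.numeric(rpois(length(inter_rows), cfg$inter_mean))]
  })
  out <- tab[count > 0, .(i, j, count)]
  setattr(out, "expected", tab[, .(i, j, GD, inter, BP, mu_log)])
  out[]
}

#' Configuration of the covariate-track generator
#'
#' Per-window values: SD fraction ~ Beta, gene density ~ Beta, DNaseI signal
#' ~ log-normal; at breakpoint-containing windows the Beta shape-1 (or the
#' log-normal scale) is multiplied by the enrichment factor, so a factor of 1
#' reproduces the background distribution exactly and a factor > 1 raises the
#' mean. Defaults emulate a genome ~5% segmental duplication, ~40% genic
#' coverage, and the reported enrichment of breakpoint loci in SDs, genes and
#' open chromatin.
#'
#' @param sd_shape1,sd_shape2 Beta shapes of the background SD fraction.
#' @param sd_enrich SD enrichment factor at breakpoint windows.
#' @param gene_shape1,gene_shape2 Beta shapes of background gene density.
#' @param gene_enrich Gene-density enrichment factor at breakpoint windows.
#' @param dnase_meanlog,dnase_sdlog Log-normal parameters of the DNase signal.
#' @param dnase_enrich Multiplicative DNase enrichment at breakpoint windows.
#' @param gap_fraction Gap fraction given to designated gap windows.
#' @param seed Integer seed.
#' @return A `track_config` list.
#' @export
track_config <- function(sd_shape1 = 0.5, sd_shape2 = 10, sd_enrich = 3,
                         gene_shape1 = 3, gene_shape2 = 4.5, gene_enrich = 1.5,
                         dnase_meanlog = log(100), dnase_sdlog = 0.5,
                         dnase_enrich = 1.5, gap_fraction = 0.6, seed = 1) {
  stop_if_not(sd_enrich > 0 && gene_enrich > 0 && dnase_enrich > 0,
              "enrichment factors must be positive")
  structure(list(sd_shape1 = sd_shape1, sd_shape2 = sd_shape2, sd_enrich = sd_enrich,
                 gene_shape1 = gene_shape1, gene_shape2 = gene_shape2,
                 gene_enrich = gene_enrich, dnase_meanlog = dnase_meanlog,
                 dnase_sdlog = dnase_sdlog, dnase_enrich = dnase_enrich,
                 gap_fraction = gap_fraction, seed = seed),
            class = "track_config")
}

#' Simulate per-window covariate tracks
#'
#' @param grid A `locus_grid`.
#' @param bp_windows Integer grid `idx` of breakpoint-containing windows
#'   (these receive the enrichment factors).
#' @param cfg A [track_config()].
#' @param gap_windows Integer grid `idx` of windows to bury under an assembly
#'   gap of `cfg$gap_fraction` (default none).
#' @return `data.table(idx, sd_frac, gene_density, dnase, gap_frac)`,
#'   seed-deterministic; fractions in `[0, 1]`, DNase >= 0.
#' @export
simulate_covariate_tracks <- function(grid, bp_windows, cfg, gap_windows = integer(0)) {
  stop_if_not(inherits(cfg, "track_config"), "cfg must be a track_config")
  gdt <- as.data.table(grid)
  n <- nrow(gdt)
  is_bp <- gdt$idx %in% bp_windows
  with_seed(cfg$seed, {
    s1 <- ifelse(is_bp, cfg$sd_shape1 * cfg$sd_enrich, cfg$sd_shape1)
    g1 <- ifelse(is_bp, cfg$gene_shape1 * cfg$gene_enrich, cfg$gene_shape1)
    dn <- rlnorm(n, cfg$dnase_meanlog, cfg$dnase_sdlog) * ifelse(is_bp, cfg$dnase_enrich, 1)
    data.table(
      idx = gdt$idx,
      sd_frac = rbeta(n, s1, cfg$sd_shape2),
      gene_density = rbeta(n, g1, cfg$gene_shape2),
      dnase = dn,
      gap_frac = ifelse(gdt$idx %in% gap_windows, cfg$gap_fraction, 0)
    )
  })
}

#' Simulate the SD multi-mapping bias on count triples
#'
#' Emulates random assignment of multi-mapping read ends among segmental
#' duplication copies: a read end falling in the SD portion of a window (with
#' probability the window's SD fraction, under the uniform-density
#' assumption) is, with probability `relocation_rate`, reassigned to a random
#' partner window sharing those SD copies (landing inside the partner's SD
#' region). Total read count is conserved. The returned triples carry an
#' exact `sdr` column — reads with at least one end inside an SD region —
#' which is what the downstream correction consumes.
#'
#' @param triples `data.table(i, j, count)`.
#' @param sd_frac Numeric vector of SD fractions indexed by window `idx`
#'   (e.g. `grid$sd_frac` for a dense grid).
#' @param families List of integer vectors: windows sharing SD copies.
#'   Windows with SD sequence but no family still accrue `sdr` but cannot
#'   relocate.
#' @param relocation_rate Probability in `[0, 1]` that an SD read end is
#'   relocated.
#' @param seed Integer seed.
#' @return `data.table(i, j, count, sdr)` with the same total count.
#' @export
simulate_sd_mapping_bias <- function(triples, sd_frac, families = list(),
                                     relocation_rate = 0.5, seed = 1) {
  stop_if_not(relocation_rate >= 0 && relocation_rate <= 1,
              "relocation_rate must lie in [0, 1]")
  tr <- as.data.table(triples)[, .(i, j, count)]
  fam_of <- new.env(parent = emptyenv())
  for (fam in families) for (w in fam) assign(as.character(w), setdiff(fam, w), envir = fam_of)
  partners <- function(w) {
    key <- as.character(w)
    if (exists(key, envir = fam_of, inherits = FALSE)) get(key, envir = fam_of) else integer(0)
  }
  fsd <- function(w) ifelse(w <= length(sd_frac), sd_frac[w], 0)
  with_seed(seed, {
    p_i <- fsd(tr$i); p_j <- fsd(tr$j)
    # per triple, split reads by which ends fall in SD sequence
    n_i_sd <- rbinom(nrow(tr), tr$count, p_i)
    n_j_sd_given <- function(nsub, pj) rbinom(length(nsub), nsub, pj)
    n_both <- n_j_sd_given(n_i_sd, p_j)
    n_i_only <- n_i_sd - n_both
    n_j_only <- n_j_sd_given(tr$count - n_i_sd, p_j)
    n_none <- tr$count - n_both - n_i_only - n_j_only
    # expand SD-incident reads; untouched reads stay aggregated
    expand <- function(n_vec, sdi, sdj) {
      k <- which(n_vec > 0)
      if (!length(k)) return(NULL)
      data.table(i = rep(tr$i[k], n_vec[k]), j = rep(tr$j[k], n_vec[k]),
                 sdi = sdi, sdj = sdj)
    }
    reads <- rbindlist(list(
      expand(n_both, TRUE, TRUE), expand(n_i_only, TRUE, FALSE), expand(n_j_only, FALSE, TRUE)
    ))
    if (!is.null(reads) && nrow(reads) > 0L) {
      relocate_end <- function(w, in_sd) {
        mov <- in_sd & runif(length(w)) < relocation_rate
        for (k in which(mov)) {
          ps <- partners(w[k])
          if (length(ps)) w[k] <- if (length(ps) == 1L) ps else sample(ps, 1L)
        }
        w
      }
      reads[, i := relocate_end(i, sdi)]
      reads[, j := relocate_end(j, sdj)]
      moved <- reads[, .(i = pmin(i, j), j = pmax(i, j))][, .(count = as.numeric(.N), sdr = as.numeric(.N)), by = .(i, j)]
    } else {
      moved <- data.table(i = integer(), j = integer(), count = numeric(), sdr = numeric())
    }
    keep <- data.table(i = tr$i, j = tr$j, count = as.numeric(n_none), sdr = 0)[count > 0]
    out <- rbindlist(list(keep, moved))[, .(count = sum(count), sdr = sum(sdr)), by = .(i, j)]
    setorder(out, i, j)
    out[]
  })
}
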