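# Association testing: nested linear models (ANCOVA) for the breakpoint
# effect on log contact counts, the rank-sum test for inter-chromosomal
# pairs, and the stratified resampling null matched on genomic distance,
# gene density and DNaseI sensitivity.
#
# Model family (natural logs; BP is the breakpoint-pair indicator):
#   M0: log(RC) ~ log(GD)
#   M1: log(RC) ~ log(GD) + BP
#   M2: log(RC) ~ log(GD) + BP + log(GD):BP
#   M3: log(RC) ~ log(GD) + log(Gcov)
#   M4: M3 + BP
#   M5: M4 + log(Gcov):BP
#   M6: log(RC) ~ log(GD) + log(DNase)
#   M7: M6 + BP
#   M8: M7 + log(DNase):BP
# Errors are assumed Gaussian and locus pairs independent; fits use ordinary
# least squares on intra-chromosomal pairs at GD >= 1 Mb.

TERM_VARS <- list(
  "log_GD" = "log_GD", "BP" = "BP", "log_GD:BP" = c("log_GD", "BP"),
  "log_Gcov" = "log_Gcov", "log_Gcov:BP" = c("log_Gcov", "BP"),
  "log_DNase" = "log_DNase", "log_DNase:BP" = c("log_DNase", "BP")
)

#' Define a linear model specification
#'
#' @param name Model label (e.g. `"M1"`).
#' @param terms Character vector of right-hand-side terms drawn from
#'   `log_GD`, `BP`, `log_GD:BP`, `log_Gcov`, `log_Gcov:BP`, `log_DNase`,
#'   `log_DNase:BP`. The response is always `log_RC`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(name, terms) {
  bad <- setdiff(terms, names(TERM_VARS))
  stop_if_not(length(bad) == 0L, "unknown model term(s): %s", paste(bad, collapse = ", "))
  structure(list(name = name, terms = terms), class = "model_spec")
}

#' The standard embedded model family M0..M8
#'
#' @return Named list of [model_spec()] objects.
#' @export
ancova_models <- function() {
  list(
    M0 = model_spec("M0", "log_GD"),
    M1 = model_spec("M1", c("log_GD", "BP")),
    M2 = model_spec("M2", c("log_GD", "BP", "log_GD:BP")),
    M3 = model_spec("M3", c("log_GD", "log_Gcov")),
    M4 = model_spec("M4", c("log_GD", "log_Gcov", "BP")),
    M5 = model_spec("M5", c("log_GD", "log_Gcov", "BP", "log_Gcov:BP")),
    M6 = model_spec("M6", c("log_GD", "log_DNase")),
    M7 = model_spec("M7", c("log_GD", "log_DNase", "BP")),
    M8 = model_spec("M8", c("log_GD", "log_DNase", "BP", "log_DNase:BP"))
  )
}

spec_vars <- function(spec) unique(c("log_RC", unlist(TERM_VARS[spec$terms], use.names = FALSE)))

model_rows <- function(table, spec) {
  vars <- setdiff(spec_vars(spec), "BP")
  ok <- !table$inter & !is.na(table$GD) & table$GD >= 1
  for (v in vars) ok <- ok & is.finite(table[[v]])
  which(ok)
}

#' Fit a model specification by ordinary least squares
#'
#' Rows used default to intra-chromosomal pairs with `GD >= 1` Mb and finite
#' values of every variable the model needs (zero corrected counts and
#' zero-density loci drop out through their `NA` logs).
#'
#' @param spec A [model_spec()].
#' @param table A `pair_table`.
#' @param rows Optional integer row indices to fit on (for nested
#'   comparisons, which require both models on identical rows).
#' @return A `fit_result`: list with `name`, `terms`, `fit` (the `lm`),
#'   `coefficients`, `n`, `rss`, `df`, `rows`.
#' @export
fit_model <- function(spec, table, rows = NULL) {
  stop_if_not(inherits(spec, "model_spec"), "spec must be a model_spec")
  table <- as.data.table(table)
  if (is.null(rows)) rows <- model_rows(table, spec)
  stop_if_not(length(rows) > length(spec$terms) + 1L,
              "not enough usable rows (%d) to fit %s", length(rows), spec$name)
  dat <- table[rows]
  if (any(grepl("BP", spec$terms))) {
    stop_if_not(length(unique(dat$BP)) == 2L,
                "degenerate BP column (all %s) in rows used for %s",
                as.character(dat$BP[1]), spec$name)
  }
  dat <- dat[, .(log_RC, log_GD,
                 BP = as.numeric(BP),
                 log_Gcov = if ("log_Gcov" %in% names(table)) log_Gcov else NA_real_,
                 log_DNase = if ("log_DNase" %in% names(table)) log_DNase else NA_real_)]
  rhs <- if (length(spec$terms)) paste(spec$terms, collapse = " + ") else "1"
  fit <- lm(as.formula(paste("log_RC ~", rhs)), data = dat)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop(sprintf("rank-deficient design for %s: collinear term(s) %s", spec$name,
                 paste(names(cf)[is.na(cf)], collapse = ", ")), call. = FALSE)
  }
  res <- list(
    name = spec$name, terms = spec$terms, fit = fit,
    coefficients = summary(fit)$coefficients,
    n = nrow(dat),
    rss = sum(fit$residuals^2),
    df = fit$df.residual,
    rows = rows
  )
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model %s: log_RC ~ %s  (n = %d, RSS = %.4g, df = %d)\n",
              x$name, paste(x$terms, collapse = " + "), x$n, x$rss, x$df))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Extra-sum-of-squares F test between two nested fits
#'
#' `F = ((RSS_small - RSS_big) / d_df) / (RSS_big / df_big)`, with the p-value
#' from the F distribution on `(d_df, df_big)`. Both fits must have been
#' estimated on identical rows and the small model's terms must be a strict
#' subset of the big model's.
#'
#' @param small,big [fit_model()] results.
#' @return A `nested_comparison` list: `f`, `df1`, `df2`, `p`, model names.
#' @export
compare_nested_models <- function(small, big) {
  stop_if_not(inherits(small, "fit_result") && inherits(big, "fit_result"),
              "both arguments must be fit_result objects")
  stop_if_not(all(small$terms %in% big$terms),
              "models are not nested: %s is not a subset of %s", small$name, big$name)
  stop_if_not(length(big$terms) > length(small$terms),
              "big model adds no term over %s: F undefined", small$name)
  stop_if_not(identical(small$rows, big$rows),
              "fits use different rows; refit both via compare_models() or a shared `rows`")
  d_df <- small$df - big$df
  f <- ((small$rss - big$rss) / d_df) / (big$rss / big$df)
  p <- pf(f, d_df, big$df, lower.tail = FALSE)
  structure(list(small = small$name, big = big$name, f = f,
                 df1 = d_df, df2 = big$df, p = p),
            class = "nested_comparison")
}

#' @export
print.nested_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: F = %.4g on (%d, %d) df, p = %.3g\n",
              x$big, x$small, x$f, x$df1, x$df2, x$p))
  invisible(x)
}

#' Fit two nested models on common rows and compare them
#'
#' Rows are those usable by the bigger model, so both fits see identical data.
#'
#' @param table A `pair_table`.
#' @param small_spec,big_spec [model_spec()]s, nested by term inclusion.
#' @return List with `small`, `big` (fit_results) and `test`
#'   (the [compare_nested_models()] result).
#' @export
compare_models <- function(table, small_spec, big_spec) {
  rows <- model_rows(as.data.table(table), big_spec)
  small <- fit_model(small_spec, table, rows = rows)
  big <- fit_model(big_spec, table, rows = rows)
  list(small = small, big = big, test = compare_nested_models(small, big))
}

#' Two-sided Wilcoxon rank-sum test on raw counts
#'
#' Used for inter-chromosomal pairs, where no genomic distance is defined.
#'
#' @param values_flagged,values_unflagged Raw corrected counts of flagged and
#'   unflagged pairs; both must be non-empty.
#' @return List with `statistic`, `p`, `n_flagged`, `n_unflagged`.
#' @export
ranksum_test <- function(values_flagged, values_unflagged) {
  stop_if_not(length(values_flagged) > 0 && length(values_unflagged) > 0,
              "both samples must be non-empty")
  wt <- wilcox.test(values_flagged, values_unflagged, alternative = "two.sided")
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_flagged = length(values_flagged), n_unflagged = length(values_unflagged))
}

#' Define a stratification scheme for the resampling null
#'
#' @param distance Use genomic-distance classes (default `TRUE`): equal-width
#'   classes in log GD between the observed intra-chromosomal minimum and
#'   maximum (left-open, right-closed, lowest closed), plus an `inter` class.
#' @param n_distance Number of intra distance classes (default 9).
#' @param gene Use gene-density classes with `gene_breaks` thresholds on the
#'   pair product `Gcov`: a class for exactly 0, then `(0, 0.1]`,
#'   `(0.1, 0.25]`, `(0.25, 1]` by default.
#' @param dnase Use DNase pair classes: each locus is `rich`/`poor` by median
#'   split of per-locus sums (or `dnase_threshold`), pairs classed
#'   `rich-rich`/`rich-poor`/`poor-poor`.
#' @param gene_breaks Upper thresholds after the zero class.
#' @param dnase_threshold Optional explicit rich/poor threshold.
#' @return A `stratum_scheme` object.
#' @export
stratum_scheme <- function(distance = TRUE, n_distance = 9, gene = FALSE,
                           dnase = FALSE, gene_breaks = c(0, 0.1, 0.25, 1),
                           dnase_threshold = NULL) {
  structure(list(distance = distance, n_distance = n_distance, gene = gene,
                 dnase = dnase, gene_breaks = gene_breaks,
                 dnase_threshold = dnase_threshold),
            class = "stratum_scheme")
}

#' Assign each locus pair to a stratum
#'
#' @param table A `pair_table`.
#' @param scheme A [stratum_scheme()].
#' @return Character vector of stratum labels (`NA` where a pair cannot be
#'   classified, e.g. a self-pair under distance classes).
#' @export
assign_strata <- function(table, scheme) {
  table <- as.data.table(table)
  n <- nrow(table)
  parts <- list()
  if (scheme$distance) {
    lab <- rep(NA_character_, n)
    lab[table$inter] <- "inter"
    ok <- !table$inter & !is.na(table$GD) & table$GD >= 1
    lg <- log(table$GD[ok])
    if (any(ok)) {
      r <- range(lg)
      if (r[1] == r[2]) {
        lab[ok] <- "D1"
      } else {
        breaks <- seq(r[1], r[2], length.out = scheme$n_distance + 1L)
        cl <- cut(lg, breaks = breaks, include.lowest = TRUE,
                  labels = paste0("D", seq_len(scheme$n_distance)))
        lab[ok] <- as.character(cl)
      }
    }
    parts$distance <- lab
  }
  if (scheme$gene) {
    stop_if_not("Gcov" %in% names(table), "scheme uses gene density but table has no Gcov")
    gb <- scheme$gene_breaks
    lab <- rep(NA_character_, n)
    g <- table$Gcov
    lab[!is.na(g) & g == 0] <- "G0"
    pos <- !is.na(g) & g > 0
    # classes (0, b1], (b1, b2], (b2, b3]
    cl <- cut(g[pos], breaks = gb, include.lowest = FALSE,
              labels = paste0("G", seq_len(length(gb) - 1L)))
    lab[pos] <- as.character(cl)
    parts$gene <- lab
  }
  if (scheme$dnase) {
    stop_if_not(all(c("d_i", "d_j") %in% names(table)),
                "scheme uses DNase but table has no per-locus d_i/d_j")
    loci <- unique(rbind(table[, .(idx = i, v = d_i)], table[, .(idx = j, v = d_j)]))
    thr <- scheme$dnase_threshold %||% median(loci$v, na.rm = TRUE)
    lev <- function(v) ifelse(v >= thr, "rich", "poor")
    li <- lev(table$d_i); lj <- lev(table$d_j)
    lab <- ifelse(is.na(li) | is.na(lj), NA_character_,
                  paste(pmin(li, lj), pmax(li, lj), sep = "-"))
    parts$dnase <- lab
  }
  stop_if_not(length(parts) > 0, "scheme has no active component")
  out <- do.call(paste, c(parts, sep = "|"))
  out[Reduce(`|`, lapply(parts, is.na))] <- NA_character_
  out
}

#' Stratified resampling test of the breakpoint effect
#'
#' Compares the mean (corrected) read count of flagged pairs with a null
#' distribution built by repeatedly drawing, in every stratum, as many
#' unflagged pairs as there are flagged pairs (without replacement within a
#' replicate), pooling the draws and recording their mean. The one-sided
#' empirical p-value with small-sample correction is
#' `(1 + #{null mean >= observed}) / (B + 1)`.
#'
#' @param table A `pair_table`.
#' @param scheme A [stratum_scheme()].
#' @param B Number of resampling replicates (default 500).
#' @param seed Optional integer seed (deterministic result).
#' @param value Column holding the count to average (default `"NRCSD"`).
#' @return A `resampling_result`: `observed`, `null` (length `B`), `p`, `B`,
#'   `n_flagged`, `strata` (per-stratum flagged/unflagged counts).
#' @export
stratified_resampling_test <- function(table, scheme, B = 500, seed = NULL,
                                       value = "NRCSD") {
  table <- as.data.table(table)
  stop_if_not(value %in% names(table), "no column '%s' in table", value)
  strata <- assign_strata(table, scheme)
  v <- table[[value]]
  usable <- !is.na(strata) & !is.na(v)
  flagged <- usable & table$BP
  stop_if_not(any(flagged), "no usable flagged pair")
  obs <- mean(v[flagged])
  tab <- data.table(stratum = strata[usable], flag = table$BP[usable],
                    row = which(usable))
  per <- tab[, .(n_flag = sum(flag), n_unflag = sum(!flag)), by = stratum]
  active <- per[n_flag > 0]
  short <- active[n_unflag < n_flag]
  stop_if_not(nrow(short) == 0L,
              "stratum '%s' has %d flagged but only %d unflagged pairs",
              short$stratum[1], short$n_flag[1], short$n_unflag[1])
  pools <- lapply(active$stratum, function(s) tab[stratum == s & flag == FALSE, row])
  ks <- active$n_flag
  k_tot <- sum(ks)
  null <- with_seed(seed, {
    sums <- matrix(0, nrow = B, ncol = length(pools))
    for (sidx in seq_along(pools)) {
      pool <- pools[[sidx]]; k <- ks[sidx]
      sums[, sidx] <- vapply(seq_len(B), function(b) sum(v[sample(pool, k)]), numeric(1))
    }
    rowSums(sums) / k_tot
  })
  p <- (1 + sum(null >= obs)) / (B + 1)
  structure(list(observed = obs, null = null, p = p, B = B,
                 n_flagged = k_tot,
                 strata = per[order(stratum)]),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("Stratified resampling: observed mean = %.4g, null mean = %.4g (B = %d), p = %.4g\n",
              x$observed, mean(x$null), x$B, x$p))
  invisible(x)
}
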