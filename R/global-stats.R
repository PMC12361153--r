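#' Weighted methylation level
#'
#' The coverage-robust WGBS summary: total methylated reads divided by
#' total reads over the qualifying sites (context match, coverage >=
#' `min_cov`, inside `region` when given). This is a read-weighted level,
#' not the mean of per-site levels; deep sites count for more.
#'
#' @param sample a [MethylomeSample].
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"ALL"` (all cytosines).
#' @param region optional list/row with `chrom`, `start`, `end` (0-based
#'   half-open) restricting the computation.
#' @param min_cov minimum site coverage; default 1 (all covered sites).
#' @return a fraction in \[0, 1\].
#' @export
weighted_methylation_level <- function(sample, context = "ALL",
                                       region = NULL, min_cov = 1L) {
  stopifnot(min_cov >= 1L)
  dt <- .qualifying_sites(sample, context, min_cov, region)
  tot <- sum(dt$meth) + sum(dt$unmeth)
  if (nrow(dt) == 0L || tot == 0L)
    stop("no qualifying sites for weighted methylation level (context ",
         context, ")")
  sum(dt$meth) / tot
}

#' Call methylcytosines by binomial test against the error rate
#'
#' A cytosine is called methylated when its methylated read count is
#' incompatible with the bisulfite non-conversion/sequencing error rate:
#' the one-sided binomial tail P(X >= meth | n = coverage, p = error_rate)
#' is computed for every site with coverage >= `min_cov`, adjusted across
#' all tested sites by Benjamini-Hochberg, and called at q <= `q_max`.
#'
#' @param sample a [MethylomeSample].
#' @param error_rate combined non-conversion + error rate (default 0.005).
#' @param min_cov minimum coverage for a testable site (default 4).
#' @param q_max BH-adjusted significance cutoff (default 0.05).
#' @return data.table of called sites (`chrom`, `pos`, `strand`, `context`,
#'   `meth`, `unmeth`, `p`, `q`).
#' @export
call_methylcytosines <- function(sample, error_rate = 0.005, min_cov = 4L,
                                 q_max = 0.05) {
  stopifnot(error_rate > 0, error_rate < 1, min_cov >= 1L)
  dt <- .qualifying_sites(sample, "ALL", min_cov)
  if (nrow(dt) == 0L) return(dt[, `:=`(p = numeric(), q = numeric())][])
  dt <- copy(dt)
  cov <- dt$meth + dt$unmeth
  dt[, p := pbinom(meth - 1L, cov, error_rate, lower.tail = FALSE)]
  dt[, q := bh_adjust(p)]
  dt[q <= q_max][]
}

#' Context proportions of called methylcytosines
#'
#' @param called data.table of called sites from [call_methylcytosines()].
#' @return named numeric vector over CG/CHG/CHH summing to 1.
#' @export
context_proportions <- function(called) {
  if (is.null(called) || nrow(called) == 0L)
    stop("no called methylcytosines; context proportions undefined")
  counts <- vapply(CONTEXTS, function(cx) sum(called$context == cx), 0)
  counts / sum(counts)
}

#' Global methylation summary of a sample
#'
#' Per-context weighted levels plus methylcytosine counts and their
#' relative context proportions, the two panels of a standard genome-wide
#' methylome overview.
#'
#' @inheritParams call_methylcytosines
#' @param level_min_cov coverage floor for the weighted levels (default 1).
#' @return list with `levels` (named per-context fractions, plus `ALL`),
#'   `mC_counts` and `proportions`.
#' @export
global_methylation_summary <- function(sample, error_rate = 0.005,
                                       min_cov = 4L, q_max = 0.05,
                                       level_min_cov = 1L) {
  levels <- vapply(c(CONTEXTS, "ALL"), function(cx)
    weighted_methylation_level(sample, cx, min_cov = level_min_cov), 0)
  called <- call_methylcytosines(sample, error_rate, min_cov, q_max)
  props <- context_proportions(called)
  counts <- vapply(CONTEXTS, function(cx) sum(called$context == cx), 0)
  list(levels = levels, mC_counts = counts, proportions = props)
}

#' Fixed-window chromosome summary
#'
#' Weighted methylation level per context in non-overlapping tiles
#' (default 100 kb), plus gene / annotation density per tile when gene
#' models or interval sets are supplied. Tiles with no qualifying site get
#' `NA`, never 0.
#'
#' @param sample a [MethylomeSample].
#' @param window_size tile width in bp (default 100000).
#' @param min_cov minimum site coverage (default 1).
#' @param genes optional gene models (see [read_gene_annotation()]); adds a
#'   `gene_density` column (fraction of tile bp covered by gene bodies).
#' @param te optional interval data.table of repeat/TE blocks; adds
#'   `te_density`.
#' @return data.table, one row per tile, with per-context level columns.
#' @export
chromosome_window_summary <- function(sample, window_size = 100000L,
                                      min_cov = 1L, genes = NULL, te = NULL) {
  tiles <- tile_windows(sample$chrom_sizes, window_size)
  dt <- .qualifying_sites(sample, "ALL", min_cov)
  dt <- copy(dt)[, win := (pos - 1L) %/% as.integer(window_size)]
  agg <- dt[, .(meth = sum(meth), total = sum(meth + unmeth)),
            by = .(chrom, win, context)]
  tiles[, win := start %/% as.integer(window_size)]
  for (cx in c(CONTEXTS, "ALL")) {
    sub <- if (cx == "ALL") {
      agg[, .(meth = sum(meth), total = sum(total)), by = .(chrom, win)]
    } else agg[context == cx]
    lv <- sub[, .(chrom, win, level = meth / total)]
    col <- paste0("level_", cx)
    tiles[lv, (col) := i.level, on = c("chrom", "win")]
  }
  if (!is.null(genes))
    tiles[, gene_density :=
            .overlap_widths(tiles, genes[, .(chrom, start, end)]) /
            (end - start)]
  if (!is.null(te))
    tiles[, te_density := .overlap_widths(tiles, te) / (end - start)]
  tiles[, win := NULL]
  tiles[]
}
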