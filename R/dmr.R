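#' DMR calling criteria
#'
#' Bundles the window-level thresholds for differential methylation calling
#' in one sequence context. Defaults follow the standard per-context scheme
#' for plant WGBS comparisons: a 200 bp window, per-base coverage >= 4, and
#' context-specific site-count / effect-size / q-value thresholds —
#' CG and CHG: >= 5 sites, |diff| >= 0.25, q <= 0.05;
#' CHH: >= 15 sites, |diff| >= 0.15, q <= 0.05;
#' all cytosines pooled (`"ALL_C"`): >= 20 sites, |diff| >= 0.2, q <= 0.05.
#'
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"ALL_C"`.
#' @param min_sites minimum qualifying cytosine positions per window, in
#'   both groups.
#' @param min_abs_diff minimum absolute difference of pooled methylation
#'   ratios.
#' @param q_max BH-adjusted p-value cutoff.
#' @param window_size window width in bp.
#' @param min_site_cov per-sample coverage needed for a site to contribute.
#' @return list of class `DmrCriteria`.
#' @export
dmr_criteria <- function(context = c("CG", "CHG", "CHH", "ALL_C"),
                         min_sites = NULL, min_abs_diff = NULL,
                         q_max = 0.05, window_size = 200L,
                         min_site_cov = 4L) {
  context <- match.arg(context)
  defaults <- list(CG = c(5L, 0.25), CHG = c(5L, 0.25),
                   CHH = c(15L, 0.15), ALL_C = c(20L, 0.20))[[context]]
  min_sites <- as.integer(min_sites %||% defaults[1L])
  min_abs_diff <- min_abs_diff %||% defaults[2L]
  stopifnot(min_sites >= 1L, min_abs_diff > 0, min_abs_diff < 1,
            q_max > 0, q_max < 1, window_size >= 1L, min_site_cov >= 1L)
  structure(list(context = context, min_sites = min_sites,
                 min_abs_diff = min_abs_diff, q_max = q_max,
                 window_size = as.integer(window_size),
                 min_site_cov = as.integer(min_site_cov)),
            class = "DmrCriteria")
}

#' Pearson chi-square test on a 2x2 methylation count table
#'
#' Uncorrected Pearson chi-square with 1 degree of freedom on the table
#' rows (group A, group B) x columns (methylated, unmethylated reads).
#' Vectorised over windows.
#'
#' @param meth_a,unmeth_a,meth_b,unmeth_b non-negative read counts.
#' @return data.table with `chi2` and upper-tail `p`.
#' @export
chisq_2x2 <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  if (any(c(meth_a, unmeth_a, meth_b, unmeth_b) < 0))
    stop("negative counts")
  ra <- meth_a + unmeth_a; rb <- meth_b + unmeth_b
  cm <- meth_a + meth_b; cu <- unmeth_a + unmeth_b
  if (any(ra == 0 | rb == 0 | cm == 0 | cu == 0))
    stop("degenerate 2x2 table (zero margin); test undefined")
  n <- ra + rb
  # chi2 = n (ad - bc)^2 / (row1 row2 col1 col2); doubles avoid overflow
  num <- (as.numeric(meth_a) * unmeth_b - as.numeric(unmeth_a) * meth_b)^2
  chi2 <- as.numeric(n) * num /
    (as.numeric(ra) * as.numeric(rb) * as.numeric(cm) * as.numeric(cu))
  data.table(chi2 = chi2, p = pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns q-values in the input order, clipped to \[0, 1\]:
#' q_(i) = min over j >= i of p_(j) * m / j over the sorted p-values.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[ord] * m / seq.int(m, 1L)))
  q[order(ord)]
}

# pooled qualifying-site window aggregation for one group of samples:
# sites are filtered per sample (coverage >= min_site_cov, context), read
# counts summed per window, n_sites = distinct (chrom,pos,strand) positions
# qualifying in >= 1 sample
.group_window_counts <- function(group, context, window_size, min_site_cov) {
  dt <- rbindlist(lapply(group, function(s)
    .qualifying_sites(s, context, min_site_cov)))
  if (nrow(dt) == 0L)
    return(data.table(chrom = character(), win = integer(),
                      n_sites = integer(), meth = numeric(),
                      total = numeric()))
  dt[, win := (pos - 1L) %/% window_size]
  counts <- dt[, .(meth = as.numeric(sum(meth)),
                   total = as.numeric(sum(meth + unmeth))),
               by = .(chrom, win)]
  ns <- unique(dt, by = c("chrom", "pos", "strand"))[, .(n_sites = .N),
                                                     by = .(chrom, win)]
  counts[ns, n_sites := i.n_sites, on = c("chrom", "win")]
  counts
}

#' Aggregate pooled methylation counts for one window
#'
#' Read counts are pooled across the group's samples over sites of the
#' requested context inside the window whose per-sample coverage meets
#' `min_site_cov`; `n_sites` counts distinct (chrom, pos, strand) positions
#' qualifying in at least one sample.
#'
#' @param group list of [MethylomeSample].
#' @param window list/row with `chrom`, `start`, `end` (0-based half-open).
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"ALL_C"`.
#' @param min_site_cov per-sample coverage threshold.
#' @return list with `n_sites`, `meth`, `total`.
#' @export
aggregate_window_counts <- function(group, window, context,
                                    min_site_cov = 4L) {
  stopifnot(length(group) >= 1L)
  dt <- rbindlist(lapply(group, function(s)
    .qualifying_sites(s, context, min_site_cov, region = window)))
  if (nrow(dt) == 0L) return(list(n_sites = 0L, meth = 0L, total = 0L))
  list(n_sites = nrow(unique(dt[, .(chrom, pos, strand)])),
       meth = sum(dt$meth), total = sum(dt$meth + dt$unmeth))
}

#' Call differentially methylated regions between two sample groups
#'
#' The genome is tiled into fixed windows; per window and group, read
#' counts of qualifying sites are pooled across replicates. Windows with at
#' least `criteria$min_sites` qualifying positions in *both* groups and a
#' non-degenerate 2x2 count table are tested by uncorrected Pearson
#' chi-square; p-values are Benjamini-Hochberg adjusted across all tested
#' windows. A window is reported as a DMR when q <= `q_max` and the
#' absolute difference of the pooled (read-weighted) group levels is at
#' least `min_abs_diff`. Windows with a zero table margin are skipped and
#' excluded from the adjustment family (counted in the `n_skipped`
#' attribute), not assigned p = 1.
#'
#' @param group_a,group_b non-empty lists of [MethylomeSample] sharing one
#'   genome (e.g. the replicates of two tissues).
#' @param criteria a [dmr_criteria()] object.
#' @param return_all if `TRUE`, return every tested window with its
#'   statistics and a logical `called` column instead of only the DMRs.
#' @return data.table of DMR records: `chrom`, `start`, `end`, `context`,
#'   `n_sites_a`, `n_sites_b`, `level_a`, `level_b`, `diff` (a - b),
#'   `chi2`, `p`, `q`. Attributes `n_tested` and `n_skipped` report the
#'   size of the testing family and the degenerate windows.
#' @export
call_dmrs <- function(group_a, group_b, criteria = dmr_criteria("CG"),
                      return_all = FALSE) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must contain at least one sample")
  cs <- group_a[[1L]]$chrom_sizes
  ws <- criteria$window_size
  a <- .group_window_counts(group_a, criteria$context, ws,
                            criteria$min_site_cov)
  b <- .group_window_counts(group_b, criteria$context, ws,
                            criteria$min_site_cov)
  tab <- merge(a, b, by = c("chrom", "win"), suffixes = c("_a", "_b"))
  tab <- tab[n_sites_a >= criteria$min_sites &
             n_sites_b >= criteria$min_sites]
  degen <- (tab$meth_a + tab$meth_b == 0) |
    (tab$total_a - tab$meth_a + tab$total_b - tab$meth_b == 0)
  n_skipped <- sum(degen)
  tab <- tab[!degen]
  if (nrow(tab) == 0L) {
    out <- data.table(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      n_sites_a = integer(), n_sites_b = integer(),
                      level_a = numeric(), level_b = numeric(),
                      diff = numeric(), chi2 = numeric(), p = numeric(),
                      q = numeric())
    setattr(out, "n_tested", 0L); setattr(out, "n_skipped", n_skipped)
    return(out)
  }
  st <- chisq_2x2(tab$meth_a, tab$total_a - tab$meth_a,
                  tab$meth_b, tab$total_b - tab$meth_b)
  tab[, `:=`(chi2 = st$chi2, p = st$p)]
  tab[, q := bh_adjust(p)]
  tab[, `:=`(level_a = meth_a / total_a, level_b = meth_b / total_b)]
  tab[, diff := level_a - level_b]
  tab[, `:=`(start = win * ws,
             end = pmin((win + 1L) * ws, as.integer(cs[chrom])),
             context = criteria$context)]
  tab[, called := q <= criteria$q_max & abs(diff) >= criteria$min_abs_diff]
  cols <- c("chrom", "start", "end", "context", "n_sites_a", "n_sites_b",
            "level_a", "level_b", "diff", "chi2", "p", "q")
  n_tested <- nrow(tab)
  out <- if (return_all) tab[, c(cols, "called"), with = FALSE]
         else tab[called == TRUE, cols, with = FALSE]
  setorder(out, chrom, start)
  setattr(out, "n_tested", n_tested)
  setattr(out, "n_skipped", n_skipped)
  out[]
}

#' Genes associated with DMRs
#'
#' A gene is DMR-associated when its gene body extended by `flank` bp on
#' each side (2 kb upstream + gene body + 2 kb downstream by default,
#' clipped at the chromosome bounds) overlaps at least one DMR by >= 1 bp.
#'
#' @param dmrs data.table of DMRs (needs `chrom`, `start`, `end`).
#' @param genes gene models (see [read_gene_annotation()]).
#' @param chrom_sizes named chromosome lengths, used for clipping.
#' @param flank flank width in bp (default 2000).
#' @return character vector of associated gene ids, sorted.
#' @export
dmr_associated_genes <- function(dmrs, genes, chrom_sizes, flank = 2000L) {
  stopifnot(flank >= 0L)
  if (nrow(dmrs) == 0L || nrow(genes) == 0L) return(character())
  ext <- copy(genes)
  ext[, `:=`(start = pmax(0L, start - as.integer(flank)),
             end = pmin(as.integer(chrom_sizes[chrom]),
                        end + as.integer(flank)))]
  hits <- findOverlaps(.as_granges(ext), .as_granges(dmrs))
  sort(unique(genes$gene_id[queryHits(hits)]))
}
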