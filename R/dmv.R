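#' DMV detection parameters
#'
#' Defaults implement the standard valley scan: 1 kb windows advanced in
#' 200 bp steps, a window qualifies when the unweighted mean of its
#' per-site methylation levels (all cytosine contexts) is below 5%, and a
#' gene is a DMV gene when at least 80% of its gene body lies in the merged
#' valley union. The site-coverage floor (4) and minimum sites per window
#' (5) guard against calling valleys from unobserved or near-empty windows.
#'
#' @param window_size scan window in bp.
#' @param step step size in bp (must not exceed `window_size`).
#' @param max_level qualifying threshold on the window mean level.
#' @param min_site_cov minimum coverage for a site to enter the mean.
#' @param min_sites_per_window minimum qualifying sites for a window to be
#'   evaluated at all.
#' @param gene_fraction gene-body fraction required for DMV-gene status.
#' @return list of class `DmvParams`.
#' @export
dmv_params <- function(window_size = 1000L, step = 200L, max_level = 0.05,
                       min_site_cov = 4L, min_sites_per_window = 5L,
                       gene_fraction = 0.8) {
  stopifnot(step >= 1L, step <= window_size, max_level > 0, max_level < 1,
            min_site_cov >= 1L, min_sites_per_window >= 1L,
            gene_fraction > 0, gene_fraction <= 1)
  structure(list(window_size = as.integer(window_size),
                 step = as.integer(step), max_level = max_level,
                 min_site_cov = as.integer(min_site_cov),
                 min_sites_per_window = as.integer(min_sites_per_window),
                 gene_fraction = gene_fraction),
            class = "DmvParams")
}

#' Mean per-site methylation level of one window
#'
#' Unweighted mean over qualifying sites (any context, coverage >=
#' `min_site_cov`) of the per-site level meth/(meth+unmeth). Distinct from
#' the read-weighted level: every observed site counts equally.
#'
#' @param sample a [MethylomeSample].
#' @param window list/row with `chrom`, `start`, `end`.
#' @param min_site_cov coverage floor.
#' @return list with `mean_level` (`NA` when no qualifying site) and
#'   `n_sites`.
#' @export
window_mean_level <- function(sample, window, min_site_cov = 4L) {
  dt <- .qualifying_sites(sample, "ALL", min_site_cov, region = window)
  if (nrow(dt) == 0L) return(list(mean_level = NA_real_, n_sites = 0L))
  list(mean_level = mean(dt$meth / (dt$meth + dt$unmeth)),
       n_sites = nrow(dt))
}

# all (chrom, win_start) sliding-window assignments of qualifying sites,
# with per-window mean level and site count; windows are [k*step,
# k*step+window_size) fully on-chromosome
.sliding_window_levels <- function(sample, params) {
  dt <- .qualifying_sites(sample, "ALL", params$min_site_cov)
  if (nrow(dt) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      mean_level = numeric(), n_sites = integer()))
  dt <- copy(dt)
  dt[, level := meth / (meth + unmeth)]
  w <- params$window_size; s <- params$step
  p0 <- dt$pos - 1L
  k_max <- p0 %/% s
  k_min <- pmax(0L, (p0 - w) %/% s + 1L)
  reps <- k_max - k_min + 1L
  idx <- rep.int(seq_len(nrow(dt)), reps)
  k <- k_min[idx] + (sequence(reps) - 1L)
  asn <- data.table(chrom = dt$chrom[idx], start = k * s,
                    level = dt$level[idx])
  asn <- asn[start + w <= as.integer(sample$chrom_sizes[chrom])]
  asn[, .(mean_level = mean(level), n_sites = .N), by = .(chrom, start)]
}

#' Detect DNA methylation valleys
#'
#' Scans the genome in overlapping windows (see [dmv_params()]), keeps
#' windows whose mean per-site level over all cytosine contexts is below
#' `max_level` (with at least `min_sites_per_window` qualifying sites), and
#' merges overlapping qualifying windows into maximal valley regions. Each
#' region reports the per-site mean level over its full span.
#'
#' @param sample a [MethylomeSample]; for a per-tissue valley map, pool the
#'   tissue's replicates first with [pool_samples()].
#' @param params a [dmv_params()] object.
#' @return data.table of valley regions: `chrom`, `start`, `end`,
#'   `n_windows_merged`, `mean_level`, sorted and pairwise non-overlapping.
#' @export
detect_dmvs <- function(sample, params = dmv_params()) {
  win <- .sliding_window_levels(sample, params)
  qual <- win[n_sites >= params$min_sites_per_window &
              mean_level < params$max_level]
  if (nrow(qual) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), n_windows_merged = integer(),
                      mean_level = numeric()))
  qual[, end := start + params$window_size]
  regions <- merge_intervals(qual[, .(chrom, start, end)])
  setnames(regions, "n_merged", "n_windows_merged")
  # site-mean level over each merged span
  sites <- .qualifying_sites(sample, "ALL", params$min_site_cov)
  sgr <- GRanges(sites$chrom, IRanges(sites$pos, sites$pos))
  hits <- findOverlaps(.as_granges(regions), sgr)
  lvl <- sites$meth[subjectHits(hits)] /
    (sites$meth[subjectHits(hits)] + sites$unmeth[subjectHits(hits)])
  means <- tapply(lvl, queryHits(hits), mean)
  regions[, mean_level := NA_real_]
  regions[as.integer(names(means)), mean_level := as.numeric(means)]
  regions[]
}

#' Genes lying in DNA methylation valleys
#'
#' A gene is a DMV gene when the cumulative overlap between its gene body
#' and the union of valley regions covers at least `gene_fraction` of the
#' gene length (boundary inclusive).
#'
#' @param dmvs valley regions from [detect_dmvs()].
#' @param genes gene models.
#' @param gene_fraction required gene-body fraction (default 0.8).
#' @return character vector of DMV gene ids, sorted.
#' @export
dmv_genes <- function(dmvs, genes, gene_fraction = 0.8) {
  if (nrow(genes) == 0L || nrow(dmvs) == 0L) return(character())
  ov <- .overlap_widths(genes[, .(chrom, start, end)],
                        dmvs[, .(chrom, start, end)])
  sort(genes$gene_id[ov / (genes$end - genes$start) >= gene_fraction])
}

#' Cross-tissue DMV gene set overlap
#'
#' @param dmv_genes_by_tissue named list (>= 2 tissues) of DMV gene id
#'   vectors.
#' @return list with `per_tissue` counts, `intersection` and `union`
#'   counts, and the shared gene ids.
#' @export
dmv_tissue_overlap <- function(dmv_genes_by_tissue) {
  stopifnot(length(dmv_genes_by_tissue) >= 2L)
  sets <- lapply(dmv_genes_by_tissue, unique)
  shared <- Reduce(intersect, sets)
  list(per_tissue = vapply(sets, length, 0L),
       intersection = length(shared),
       union = length(unique(unlist(sets))),
       shared_genes = sort(shared))
}
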