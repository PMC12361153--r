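#' Tile chromosomes into fixed, non-overlapping windows
#'
#' Windows start at 0; the final partial window is included (truncated to
#' the chromosome end). This is the tiling used by the DMR caller (200 bp)
#' and the chromosome-scale summaries (100 kb).
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param window_size window width in bp.
#' @return data.table with `chrom`, `start`, `end` (0-based half-open).
#' @export
tile_windows <- function(chrom_sizes, window_size) {
  stopifnot(window_size >= 1)
  window_size <- as.integer(window_size)
  rbindlist(lapply(names(chrom_sizes), function(ch) {
    len <- as.integer(chrom_sizes[[ch]])
    starts <- seq.int(0L, len - 1L, by = window_size)
    data.table(chrom = ch, start = starts,
               end = pmin(starts + window_size, len))
  }))
}

#' Sliding windows over chromosomes
#'
#' Windows `[k*step, k*step + window_size)` for every `k` whose window fits
#' entirely on the chromosome; partial trailing windows are not emitted,
#' because a truncated window would change the meaning of a mean-level
#' threshold.
#'
#' @inheritParams tile_windows
#' @param step step size in bp (<= `window_size` for overlapping scans).
#' @return data.table with `chrom`, `start`, `end`.
#' @export
sliding_windows <- function(chrom_sizes, window_size, step) {
  stopifnot(step >= 1, window_size >= 1)
  window_size <- as.integer(window_size); step <- as.integer(step)
  rbindlist(lapply(names(chrom_sizes), function(ch) {
    len <- as.integer(chrom_sizes[[ch]])
    if (len < window_size)
      return(data.table(chrom = character(), start = integer(),
                        end = integer()))
    starts <- seq.int(0L, len - window_size, by = step)
    data.table(chrom = ch, start = starts, end = starts + window_size)
  }))
}

# 0-based half-open data.table -> GRanges (1-based internal shift)
.as_granges <- function(dt) {
  GRanges(dt$chrom, IRanges(dt$start + 1L, dt$end))
}

# GRanges -> 0-based half-open data.table
.as_intervals <- function(gr) {
  data.table(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L, end = end(gr))
}

#' Merge overlapping intervals into their union
#'
#' @param intervals data.table with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return merged, sorted intervals with a column `n_merged` counting how
#'   many input intervals each union region absorbed.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), n_merged = integer()))
  gr <- .as_granges(intervals)
  red <- reduce(gr)
  hits <- findOverlaps(red, gr)
  out <- .as_intervals(red)
  out[, n_merged := tabulate(queryHits(hits), nbins = length(red))]
  setorder(out, chrom, start)
  out[]
}

# total bp of intersection between each query interval and a subject union
.overlap_widths <- function(query, subject) {
  if (nrow(query) == 0L) return(integer())
  if (nrow(subject) == 0L) return(rep(0L, nrow(query)))
  q <- .as_granges(query)
  s <- reduce(.as_granges(subject))
  hits <- findOverlaps(q, s)
  w <- width(pintersect(q[queryHits(hits)], s[subjectHits(hits)]))
  out <- rep(0L, nrow(query))
  agg <- tapply(w, queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}
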