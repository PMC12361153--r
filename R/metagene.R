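#' Strand-aware metagene methylation profile
#'
#' Averages methylation across a gene set in the classic TSS/TES layout:
#' fixed-width flank bins upstream, gene bodies rescaled to a fixed number
#' of bins, fixed-width flank bins downstream. Minus-strand genes are
#' oriented 5' to 3' so bin 0 is always the far upstream end. Per bin and
#' sequence context, read counts of all sites from all genes falling in the
#' bin are pooled and the read-weighted level reported (bins with no reads
#' are `NA`).
#'
#' @param sample a [MethylomeSample] (pool replicates first for a
#'   per-tissue profile).
#' @param genes gene models; genes shorter than `body_bins` bp are skipped
#'   with a warning.
#' @param flank flank width in bp on each side (default 2000); must be a
#'   multiple of the flank bin counts.
#' @param upstream_bins,body_bins,downstream_bins bin counts (defaults
#'   20/60/20).
#' @param min_cov minimum site coverage (default 1).
#' @return object of class `MetageneProfile`: list with `levels` (context x
#'   bin matrix over `C`, `CG`, `CHG`, `CHH`; `C` pools all contexts),
#'   `meth`/`total` count matrices, `n_genes`, and the bin configuration.
#' @export
metagene_profile <- function(sample, genes, flank = 2000L,
                             upstream_bins = 20L, body_bins = 60L,
                             downstream_bins = 20L, min_cov = 1L) {
  stopifnot(nrow(genes) > 0L, flank %% upstream_bins == 0L,
            flank %% downstream_bins == 0L)
  flank <- as.integer(flank)
  U <- as.integer(upstream_bins); B <- as.integer(body_bins)
  D <- as.integer(downstream_bins)
  nbins <- U + B + D
  genes <- as.data.table(genes)
  short <- genes$end - genes$start < B
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than body_bins bp skipped")
    genes <- genes[!short]
  }
  if (nrow(genes) == 0L) stop("no usable genes for metagene profile")
  sites <- .qualifying_sites(sample, "ALL", min_cov)
  ext <- genes[, .(chrom, start = pmax(0L, start - flank),
                   end = end + flank)]
  hits <- findOverlaps(GRanges(sites$chrom, IRanges(sites$pos, sites$pos)),
                       .as_granges(ext))
  si <- queryHits(hits); gi <- subjectHits(hits)
  p0 <- sites$pos[si] - 1L
  gs <- genes$start[gi]; ge <- genes$end[gi]
  glen <- ge - gs
  plus <- genes$strand[gi] == "+"
  ubw <- flank %/% U; dbw <- flank %/% D
  bin <- integer(length(si))
  in_up <- ifelse(plus, p0 < gs, p0 >= ge)
  in_body <- p0 >= gs & p0 < ge
  in_down <- !in_up & !in_body
  bin[in_up & plus] <- (p0 - (gs - flank))[in_up & plus] %/% ubw
  bin[in_up & !plus] <- (ge + flank - 1L - p0)[in_up & !plus] %/% ubw
  # body bin: floor(frac * B) from the 5' end; minus strand is the exact
  # mirror of the plus-strand assignment so strand reversal reverses bins
  bplus <- pmin((as.numeric(p0 - gs) * B) %/% glen, B - 1)
  bin[in_body & plus] <- U + bplus[in_body & plus]
  bin[in_body & !plus] <- U + (B - 1 - bplus)[in_body & !plus]
  bin[in_down & plus] <- U + B + (p0 - ge)[in_down & plus] %/% dbw
  bin[in_down & !plus] <- U + B + (gs - 1L - p0)[in_down & !plus] %/% dbw
  asn <- data.table(bin = as.integer(bin), context = sites$context[si],
                    meth = sites$meth[si],
                    total = sites$meth[si] + sites$unmeth[si])
  asn <- asn[bin >= 0L & bin < nbins]
  rows <- c("C", CONTEXTS)
  meth <- total <- matrix(0, nrow = length(rows), ncol = nbins,
                          dimnames = list(rows, NULL))
  agg <- asn[, .(meth = sum(meth), total = sum(total)),
             by = .(context, bin)]
  for (cx in CONTEXTS) {
    sub <- agg[context == cx]
    meth[cx, sub$bin + 1L] <- sub$meth
    total[cx, sub$bin + 1L] <- sub$total
  }
  meth["C", ] <- colSums(meth[CONTEXTS, , drop = FALSE])
  total["C", ] <- colSums(total[CONTEXTS, , drop = FALSE])
  levels <- meth / total  # 0/0 -> NaN
  levels[total == 0] <- NA_real_
  structure(list(levels = levels, meth = meth, total = total,
                 n_genes = nrow(genes), flank = flank, upstream_bins = U,
                 body_bins = B, downstream_bins = D),
            class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat(sprintf("MetageneProfile: %d genes, %d+%d+%d bins (flank %d bp)\n",
              x$n_genes, x$upstream_bins, x$body_bins, x$downstream_bins,
              x$flank))
  invisible(x)
}

#' Tidy table of a metagene profile
#'
#' @param profile a [metagene_profile()] result.
#' @return data.table with `context`, `bin` (0-based), `segment`
#'   (upstream/body/downstream), `level`, `meth`, `total`.
#' @export
metagene_table <- function(profile) {
  nb <- ncol(profile$levels)
  seg <- rep(c("upstream", "body", "downstream"),
             c(profile$upstream_bins, profile$body_bins,
               profile$downstream_bins))
  rbindlist(lapply(rownames(profile$levels), function(cx)
    data.table(context = cx, bin = seq_len(nb) - 1L, segment = seg,
               level = profile$levels[cx, ], meth = profile$meth[cx, ],
               total = profile$total[cx, ])))
}
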