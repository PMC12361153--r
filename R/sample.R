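#' Construct a methylome sample
#'
#' A `MethylomeSample` bundles the per-cytosine methylation calls of one
#' tissue/replicate with the chromosome sizes of its genome. Sites are
#' strand-resolved: the two cytosines of a symmetric CG dinucleotide are
#' kept as independent sites, the native representation of the cytosine
#' report.
#'
#' @param sample_id unique sample label, e.g. `"R1"`.
#' @param tissue tissue label, e.g. `"root"`.
#' @param replicate replicate number within the tissue.
#' @param sites data.frame/data.table with columns `chrom`, `pos` (1-based),
#'   `strand` (`"+"`/`"-"`), `context` (`"CG"`, `"CHG"`, `"CHH"`), `meth`,
#'   `unmeth` (non-negative read counts). Zero-coverage sites are allowed;
#'   they are filtered by coverage thresholds downstream, not at load time.
#' @param chrom_sizes named numeric vector of chromosome lengths in bp. Its
#'   order defines the chromosome sort order throughout the package.
#' @return an object of class `MethylomeSample` with sites sorted by
#'   (chrom, pos, strand).
#' @export
MethylomeSample <- function(sample_id, tissue, replicate, sites, chrom_sizes) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            is.character(tissue), length(tissue) == 1L)
  replicate <- as.integer(replicate)
  sites <- as.data.table(sites)
  req <- c("chrom", "pos", "strand", "context", "meth", "unmeth")
  miss <- setdiff(req, names(sites))
  if (length(miss)) stop("sites is missing columns: ", paste(miss, collapse = ", "))
  sites <- sites[, req, with = FALSE]
  sites[, `:=`(chrom = as.character(chrom), pos = as.integer(pos),
               strand = as.character(strand), context = as.character(context),
               meth = as.integer(meth), unmeth = as.integer(unmeth))]
  if (nrow(sites)) {
    if (any(sites$meth < 0L) || any(sites$unmeth < 0L))
      stop("negative read counts in sites")
    bad <- setdiff(unique(sites$context), CONTEXTS)
    if (length(bad)) stop("unknown context(s): ", paste(bad, collapse = ", "))
    if (!all(sites$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  if (is.null(names(chrom_sizes)) || anyDuplicated(names(chrom_sizes)))
    stop("chrom_sizes must be a uniquely named vector")
  unk <- setdiff(unique(sites$chrom), names(chrom_sizes))
  if (length(unk)) stop("sites on chromosomes absent from chrom_sizes: ",
                        paste(unk, collapse = ", "))
  if (nrow(sites)) {
    over <- sites$pos > chrom_sizes[sites$chrom]
    if (any(over))
      stop("site position exceeds chromosome length at row(s) ",
           paste(head(which(over), 3L), collapse = ", "))
  }
  sites[, chrom := factor(chrom, levels = names(chrom_sizes))]
  setorder(sites, chrom, pos, strand)
  sites[, chrom := as.character(chrom)]
  structure(
    list(sample_id = sample_id, tissue = tissue, replicate = replicate,
         sites = sites, chrom_sizes = chrom_sizes),
    class = "MethylomeSample")
}

#' @export
print.MethylomeSample <- function(x, ...) {
  cat(sprintf("MethylomeSample '%s' (tissue %s, rep %d): %s sites on %d chromosome(s)\n",
              x$sample_id, x$tissue, x$replicate,
              format(nrow(x$sites), big.mark = ","), length(x$chrom_sizes)))
  invisible(x)
}

#' Pool replicate methylomes by summing read counts per site
#'
#' Produces one methylome per tissue from its replicates: read counts are
#' summed over samples at each (chrom, pos, strand) site. This is the
#' pooling used before DMV detection and metagene profiling, where a single
#' per-tissue methylome is wanted.
#'
#' @param samples list of [MethylomeSample] sharing one genome.
#' @param sample_id,tissue labels for the pooled sample; default derived
#'   from the first input.
#' @return a [MethylomeSample] with summed counts (replicate set to 0).
#' @export
pool_samples <- function(samples, sample_id = NULL, tissue = NULL) {
  stopifnot(length(samples) >= 1L)
  cs <- samples[[1L]]$chrom_sizes
  for (s in samples) {
    if (!identical(names(s$chrom_sizes), names(cs)))
      stop("samples have differing chromosome sets")
  }
  tissue <- tissue %||% samples[[1L]]$tissue
  sample_id <- sample_id %||% paste0(tissue, "_pooled")
  all <- rbindlist(lapply(samples, `[[`, "sites"))
  pooled <- all[, .(meth = sum(meth), unmeth = sum(unmeth),
                    context = context[1L]),
                by = .(chrom, pos, strand)]
  MethylomeSample(sample_id, tissue, 0L, pooled, cs)
}

# qualifying sites of a sample: context filter ("CG"/"CHG"/"CHH"/"ALL"),
# minimum coverage, optional 0-based half-open region restriction
.qualifying_sites <- function(sample, context = "ALL", min_cov = 1L,
                              region = NULL) {
  dt <- sample$sites
  keep <- (dt$meth + dt$unmeth) >= min_cov
  if (!context %in% c("ALL", "ALL_C"))
    keep <- keep & dt$context == context
  if (!is.null(region)) {
    keep <- keep & dt$chrom == region$chrom &
      dt$pos > region$start & dt$pos <= region$end
  }
  dt[keep]
}
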