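#' Read a per-cytosine methylation report
#'
#' Parses the 7-column cytosine report emitted by Bismark-style methylation
#' callers (`CX_report`): chromosome, 1-based position, strand, methylated
#' read count, unmethylated read count, sequence context (CG/CHG/CHH) and
#' trinucleotide. Zero-coverage sites are retained; they are removed later
#' by coverage filters, not at load time.
#'
#' @param path path to a tab-separated cytosine report.
#' @param sample_id,tissue,replicate sample labels (see [MethylomeSample]).
#' @param chrom_sizes named vector of chromosome lengths in bp.
#' @return a [MethylomeSample].
#' @export
read_cytosine_report <- function(path, sample_id, tissue, replicate,
                                 chrom_sizes) {
  if (!file.exists(path)) stop("cytosine report not found: ", path)
  dt <- if (file.size(path) == 0L) data.table()
        else fread(path, header = FALSE, sep = "\t",
                   colClasses = "character", fill = TRUE)
  if (nrow(dt) == 0L) {
    empty <- data.table(chrom = character(), pos = integer(),
                        strand = character(), context = character(),
                        meth = integer(), unmeth = integer())
    return(MethylomeSample(sample_id, tissue, replicate, empty, chrom_sizes))
  }
  if (ncol(dt) < 6L)
    stop("cytosine report must have >= 6 tab-separated columns: ", path)
  bad_field <- which(dt[[1]] == "" | dt[[2]] == "" | dt[[4]] == "" | dt[[5]] == "")
  if (length(bad_field))
    stop("malformed cytosine report line ", bad_field[1L], " in ", path)
  pos <- suppressWarnings(as.integer(dt[[2]]))
  meth <- suppressWarnings(as.integer(dt[[4]]))
  unmeth <- suppressWarnings(as.integer(dt[[5]]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(unmeth))
  if (length(bad))
    stop("malformed cytosine report line ", bad[1L], " in ", path,
         " (non-numeric position or count)")
  ctx <- dt[[6]]
  bad_ctx <- which(!ctx %in% CONTEXTS)
  if (length(bad_ctx))
    stop("unknown context '", ctx[bad_ctx[1L]], "' at line ", bad_ctx[1L],
         " in ", path)
  if (!all(dt[[3]] %in% c("+", "-")))
    stop("invalid strand field in ", path)
  sites <- data.table(chrom = dt[[1]], pos = pos, strand = dt[[3]],
                      context = ctx, meth = meth, unmeth = unmeth)
  MethylomeSample(sample_id, tissue, replicate, sites, chrom_sizes)
}

#' Write a methylome sample as a cytosine report
#'
#' Inverse of [read_cytosine_report()]; the 7th (trinucleotide) column is
#' emitted as the context because the underlying sequence is not stored.
#'
#' @param sample a [MethylomeSample].
#' @param path output path.
#' @export
write_cytosine_report <- function(sample, path) {
  dt <- sample$sites[, .(chrom, pos, strand, meth, unmeth, context,
                         trinuc = context)]
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED6 or GFF3
#'
#' Both dialects are normalised to 0-based half-open coordinates. GFF3 input
#' is restricted to `gene` features; the gene id is taken from the `ID=`
#' attribute (falling back to `Name=`).
#'
#' @param path annotation file; format detected from the extension
#'   (`.bed` vs `.gff`/`.gff3`), falling back to content sniffing.
#' @return data.table of gene models with columns `gene_id`, `chrom`,
#'   `start` (0-based), `end` (exclusive), `strand`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation not found: ", path)
  ext <- tolower(tools::file_ext(path))
  is_gff <- ext %in% c("gff", "gff3") ||
    (ext != "bed" && length(grep("\t[^\t]*\tgene\t", readLines(path, n = 50L))) > 0)
  if (is_gff) {
    lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
    if (!length(lines)) stop("no feature lines in GFF3: ", path)
    dt <- fread(text = lines, header = FALSE, sep = "\t", fill = TRUE,
                colClasses = "character")
    if (ncol(dt) < 9L) stop("GFF3 must have 9 columns: ", path)
    dt <- dt[dt[[3]] == "gene"]
    if (nrow(dt) == 0L) stop("no gene features in GFF3: ", path)
    id <- sub(".*ID=([^;]+).*", "\\1", dt[[9]])
    noid <- !grepl("ID=", dt[[9]])
    id[noid] <- sub(".*Name=([^;]+).*", "\\1", dt[[9]][noid])
    genes <- data.table(gene_id = id, chrom = dt[[1]],
                        start = as.integer(dt[[4]]) - 1L,
                        end = as.integer(dt[[5]]), strand = dt[[7]])
  } else {
    dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character")
    if (ncol(dt) < 6L) stop("BED annotation must have 6 columns: ", path)
    genes <- data.table(gene_id = dt[[4]], chrom = dt[[1]],
                        start = as.integer(dt[[2]]),
                        end = as.integer(dt[[3]]), strand = dt[[6]])
  }
  if (anyNA(genes$start) || anyNA(genes$end))
    stop("non-numeric coordinates in annotation: ", path)
  if (any(genes$end <= genes$start))
    stop("gene with end <= start after coordinate conversion: ",
         paste(genes$gene_id[genes$end <= genes$start][1L]))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in annotation: ",
         genes$gene_id[duplicated(genes$gene_id)][1L])
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  setorder(genes, chrom, start)
  genes[]
}

#' Read a gene-by-tissue expression table
#'
#' @param path TSV with header; first column gene ids, remaining columns
#'   tissue labels, values non-negative abundances (RPKM/FPKM).
#' @return numeric matrix, genes as rownames, tissues as colnames.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  dt <- fread(path, header = TRUE, sep = "\t")
  if (ncol(dt) < 2L) stop("expression table needs >= 1 tissue column: ", path)
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated gene row in expression table: ",
         ids[duplicated(ids)][1L])
  m <- as.matrix(dt[, -1L, with = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyNA(m)) stop("missing values in expression table: ", path)
  if (any(m < 0)) stop("negative abundance in expression table: ", path)
  m
}

#' Write genomic intervals as BED
#'
#' Intervals are written 0-based half-open, sorted by (chrom, start) with
#' chromosome order taken from `chrom_order` when given, otherwise
#' lexicographic.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optional
#'   `name`, `score`, `strand` columns.
#' @param path output path.
#' @param chrom_order optional character vector declaring chromosome order.
#' @export
write_intervals_bed <- function(intervals, path, chrom_order = NULL) {
  dt <- as.data.table(intervals)
  if (nrow(dt) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(dt)))
  if (any(dt$end <= dt$start)) stop("interval with end <= start")
  lev <- chrom_order %||% sort(unique(dt$chrom))
  unk <- setdiff(unique(dt$chrom), lev)
  if (length(unk)) stop("chromosome(s) absent from declared order: ",
                        paste(unk, collapse = ", "))
  dt[, .ord := match(chrom, lev)]
  setorder(dt, .ord, start)
  dt[, .ord := NULL]
  out <- data.table(dt$chrom, as.integer(dt$start), as.integer(dt$end),
                    if ("name" %in% names(dt)) dt$name else ".",
                    if ("score" %in% names(dt)) dt$score else 0,
                    if ("strand" %in% names(dt)) dt$strand else ".")
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED3+ file.
#' @return data.table with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_intervals_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  dt <- fread(path, header = FALSE, sep = "\t")
  out <- data.table(chrom = as.character(dt[[1]]),
                    start = as.integer(dt[[2]]), end = as.integer(dt[[3]]))
  if (ncol(dt) >= 4L) out[, name := as.character(dt[[4]])]
  if (ncol(dt) >= 5L) out[, score := dt[[5]]]
  if (ncol(dt) >= 6L) out[, strand := as.character(dt[[6]])]
  out[]
}
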