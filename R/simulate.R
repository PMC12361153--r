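#' Specify a synthetic methylome landscape
#'
#' A landscape plan is the complete, seeded description of a simulated
#' study: chromosome sizes; methylation compartments (TE-like blocks, gene
#' regions, valleys, background) with per-class per-context methylation
#' probabilities; planted differentially methylated windows with
#' tissue-specific probabilities; gene models with planted expression
#' classes; and the sampling model (Poisson coverage, beta-binomial
#' site-level noise). Everything downstream — cytosine reports, expression
#' table, ground truth — is a deterministic function of the plan and its
#' seed.
#'
#' @param chrom_sizes named chromosome lengths in bp.
#' @param compartments data.table `chrom`, `start`, `end`, `class`
#'   (0-based half-open; classes in `rownames(class_probs)`); bases not
#'   covered by any compartment default to `"background"`.
#' @param class_probs numeric matrix, rows = compartment classes, columns
#'   = `CG`, `CHG`, `CHH`; entries in \[0, 1\].
#' @param planted_dmr_windows data.table `chrom`, `start`, `end`,
#'   `context`, plus one `p_<tissue>` column per tissue; overrides the
#'   compartment probability for that context inside the window. May be
#'   empty.
#' @param genes gene models with an extra `class` column (one of
#'   `root_exclusive`, `leaf_exclusive`, `root_preferential`,
#'   `leaf_preferential`, `constitutive`).
#' @param tissues tissue labels (default root, leaf).
#' @param n_replicates replicates per tissue (default 3).
#' @param mean_coverage Poisson mean read depth per site per sample
#'   (default 10).
#' @param beta_dispersion beta concentration for site-level noise around
#'   the compartment mean (default 50; larger = less dispersion).
#' @param preferential_ratio min/max expression ratio of preferential
#'   genes (default 0.005, i.e. true tau 0.995).
#' @param seed integer seed; fixed seed implies byte-identical outputs.
#' @return list of class `LandscapePlan`.
#' @export
landscape_plan <- function(chrom_sizes, compartments, class_probs,
                           planted_dmr_windows = NULL, genes = NULL,
                           tissues = c("root", "leaf"), n_replicates = 3L,
                           mean_coverage = 10, beta_dispersion = 50,
                           preferential_ratio = 0.005, seed = 1L) {
  stopifnot(!is.null(names(chrom_sizes)), mean_coverage > 0,
            beta_dispersion > 0, length(tissues) >= 2L)
  compartments <- as.data.table(compartments)
  stopifnot(all(compartments$class %in% rownames(class_probs)),
            all(colnames(class_probs) == CONTEXTS),
            all(class_probs >= 0 & class_probs <= 1),
            "background" %in% rownames(class_probs))
  if (nrow(compartments) &&
      any(compartments$end > chrom_sizes[compartments$chrom]))
    stop("compartment outside chromosome bounds")
  if (is.null(planted_dmr_windows))
    planted_dmr_windows <- data.table(chrom = character(),
                                      start = integer(), end = integer(),
                                      context = character())
  planted_dmr_windows <- as.data.table(planted_dmr_windows)
  if (nrow(planted_dmr_windows)) {
    pcols <- paste0("p_", tissues)
    stopifnot(all(pcols %in% names(planted_dmr_windows)))
  }
  if (!is.null(genes)) genes <- as.data.table(genes)
  structure(list(chrom_sizes = chrom_sizes, compartments = compartments,
                 class_probs = class_probs,
                 planted_dmr_windows = planted_dmr_windows, genes = genes,
                 tissues = tissues, n_replicates = as.integer(n_replicates),
                 mean_coverage = mean_coverage,
                 beta_dispersion = beta_dispersion,
                 preferential_ratio = preferential_ratio,
                 seed = as.integer(seed)),
            class = "LandscapePlan")
}

#' Default demonstration landscape
#'
#' Three 200 kb chromosomes, each carrying two hypermethylated TE-like
#' blocks, a 20 kb moderately methylated gene region, four planted 3 kb
#' methylation valleys, twenty planted CG-differential 200 bp windows
#' (root 0.75 vs leaf 0.25), and 15 genes: one root-exclusive gene inside
#' each valley, eight constitutive genes in the gene region, and three
#' background genes (leaf-exclusive, leaf-preferential,
#' root-preferential). Two tissues with three replicates each at 10x mean
#' coverage. The whole dataset simulates in seconds.
#'
#' @param seed integer seed.
#' @return a [landscape_plan()].
#' @export
default_landscape_plan <- function(seed = 1L) {
  chroms <- paste0("chr", 1:3)
  cs <- setNames(rep(200000L, 3L), chroms)
  probs <- rbind(background  = c(0.60, 0.45, 0.08),
                 TE_block    = c(0.95, 0.80, 0.12),
                 gene_region = c(0.25, 0.08, 0.03),
                 valley      = c(0.005, 0.005, 0.005))
  colnames(probs) <- CONTEXTS
  valley_starts <- c(40000L, 60000L, 80000L, 160000L)
  comp <- rbindlist(lapply(chroms, function(ch) rbind(
    data.table(chrom = ch, start = c(10000L, 120000L),
               end = c(30000L, 150000L), class = "TE_block"),
    data.table(chrom = ch, start = 95000L, end = 115000L,
               class = "gene_region"),
    data.table(chrom = ch, start = valley_starts,
               end = valley_starts + 3000L, class = "valley"))))
  dmr_starts <- 166000L + 400L * (0:19)
  dmrs <- rbindlist(lapply(chroms, function(ch)
    data.table(chrom = ch, start = dmr_starts, end = dmr_starts + 200L,
               context = "CG", p_root = 0.75, p_leaf = 0.25)))
  genes <- rbindlist(lapply(seq_along(chroms), function(i) {
    ch <- chroms[i]
    g_valley <- data.table(
      gene_id = sprintf("%s_vg%d", ch, seq_along(valley_starts)),
      chrom = ch, start = valley_starts + 500L,
      end = valley_starts + 2500L, class = "root_exclusive")
    g_body <- data.table(
      gene_id = sprintf("%s_cg%d", ch, 1:8), chrom = ch,
      start = 95500L + 2500L * (0:7), end = 97000L + 2500L * (0:7),
      class = "constitutive")
    g_bg <- data.table(
      gene_id = sprintf("%s_bg%d", ch, 1:3), chrom = ch,
      start = c(185000L, 188000L, 191000L),
      end = c(186500L, 189500L, 192500L),
      class = c("leaf_exclusive", "leaf_preferential",
                "root_preferential"))
    rbind(g_valley, g_body, g_bg)
  }))
  genes[, strand := rep_len(c("+", "-"), .N)]
  setcolorder(genes, c("gene_id", "chrom", "start", "end", "strand",
                       "class"))
  landscape_plan(cs, comp, probs, dmrs, genes, seed = seed)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# derive CG/CHG/CHH context of every cytosine on both strands of a
# character-vector chromosome; cytosines without a complete strand-relative
# trinucleotide (within 2 bp of the 3' end) are omitted
.catalog_chrom <- function(bases, chrom) {
  n <- length(bases)
  plus <- which(bases == "C")
  plus <- plus[plus <= n - 2L]
  ctx_p <- rep("CHH", length(plus))
  ctx_p[bases[plus + 2L] == "G"] <- "CHG"
  ctx_p[bases[plus + 1L] == "G"] <- "CG"
  minus <- which(bases == "G")
  minus <- minus[minus >= 3L]
  ctx_m <- rep("CHH", length(minus))
  ctx_m[bases[minus - 2L] == "C"] <- "CHG"
  ctx_m[bases[minus - 1L] == "C"] <- "CG"
  out <- data.table(chrom = chrom, pos = c(plus, minus),
                    strand = rep(c("+", "-"), c(length(plus), length(minus))),
                    context = c(ctx_p, ctx_m))
  setorder(out, pos, strand)
  out
}

#' Simulate a genome and its cytosine catalog
#'
#' Draws a seeded random nucleotide sequence per chromosome and catalogues
#' every cytosine on both strands with its sequence context derived from
#' the strand-relative trinucleotide: CG when followed by G, CHG for C-H-G,
#' else CHH (H = A, C or T) — the cytosine-report convention.
#'
#' @param plan a [landscape_plan()].
#' @return list with `fasta` (named character vector of sequences) and
#'   `catalog` (data.table `chrom`, `pos` 1-based, `strand`, `context`).
#' @export
simulate_genome <- function(plan) {
  set.seed(plan$seed)
  fasta <- lapply(names(plan$chrom_sizes), function(ch)
    sample(c("A", "C", "G", "T"), plan$chrom_sizes[[ch]], replace = TRUE))
  names(fasta) <- names(plan$chrom_sizes)
  catalog <- rbindlist(lapply(names(fasta), function(ch)
    .catalog_chrom(fasta[[ch]], ch)))
  catalog[, chrom := factor(chrom, levels = names(plan$chrom_sizes))]
  setorder(catalog, chrom, pos, strand)
  catalog[, chrom := as.character(chrom)]
  list(fasta = vapply(fasta, paste, "", collapse = ""), catalog = catalog)
}

#' Write simulated chromosomes as FASTA
#'
#' @param fasta named character vector of sequences (from
#'   [simulate_genome()]).
#' @param path output path.
#' @export
write_genome_fasta <- function(fasta, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(fasta), path)
  invisible(path)
}

# per-site true methylation probability for one tissue: compartment class
# probability by context, overridden inside planted DMR windows
.site_probs <- function(plan, catalog, tissue) {
  p <- plan$class_probs["background", ][catalog$context]
  comp <- plan$compartments
  if (nrow(comp)) {
    sgr <- GRanges(catalog$chrom, IRanges(catalog$pos, catalog$pos))
    hits <- findOverlaps(sgr, .as_granges(comp))
    cls <- comp$class[subjectHits(hits)]
    p[queryHits(hits)] <-
      plan$class_probs[cbind(cls, catalog$context[queryHits(hits)])]
  }
  pw <- plan$planted_dmr_windows
  if (nrow(pw)) {
    sgr <- GRanges(catalog$chrom, IRanges(catalog$pos, catalog$pos))
    hits <- findOverlaps(sgr, .as_granges(pw))
    match_ctx <- catalog$context[queryHits(hits)] ==
      pw$context[subjectHits(hits)]
    p[queryHits(hits)[match_ctx]] <-
      pw[[paste0("p_", tissue)]][subjectHits(hits)[match_ctx]]
  }
  unname(p)
}

.derive_seed <- function(seed, tissue, replicate) {
  h <- sum(utf8ToInt(tissue)) %% 1000L
  as.integer((as.numeric(seed) * 10007 + h * 101 + replicate) %% 2147483647)
}

#' Simulate one WGBS methylome sample
#'
#' Per catalogued cytosine: the true level is drawn from a beta
#' distribution centred on its compartment-by-context probability
#' (concentration = `beta_dispersion`; independent across samples, so
#' replicates vary realistically), overridden inside planted DMR windows by
#' the tissue-specific probability; coverage is Poisson(`mean_coverage`)
#' and methylated reads binomial(coverage, level). Zero-coverage sites are
#' kept, as in a real cytosine report. The random stream is namespaced by
#' (plan seed, tissue, replicate).
#'
#' @param plan a [landscape_plan()].
#' @param catalog cytosine catalog from [simulate_genome()].
#' @param tissue,replicate sample identity.
#' @param path optional: also write the sample as a cytosine report.
#' @return a [MethylomeSample] with id `<tissue><replicate>`.
#' @export
sample_methylome <- function(plan, catalog, tissue, replicate, path = NULL) {
  stopifnot(tissue %in% plan$tissues)
  p <- .site_probs(plan, catalog, tissue)
  set.seed(.derive_seed(plan$seed, tissue, replicate))
  n <- nrow(catalog)
  conc <- plan$beta_dispersion
  level <- numeric(n)
  mid <- p > 0 & p < 1
  level[mid] <- rbeta(sum(mid), p[mid] * conc, (1 - p[mid]) * conc)
  level[p >= 1] <- 1
  cov <- rpois(n, plan$mean_coverage)
  meth <- rbinom(n, cov, level)
  sites <- data.table(chrom = catalog$chrom, pos = catalog$pos,
                      strand = catalog$strand, context = catalog$context,
                      meth = meth, unmeth = cov - meth)
  s <- MethylomeSample(paste0(tissue, replicate), tissue,
                       as.integer(replicate), sites, plan$chrom_sizes)
  if (!is.null(path)) write_cytosine_report(s, path)
  s
}

#' Simulate a gene-by-tissue expression matrix with planted specificity
#'
#' Each gene gets a log-normal baseline abundance; its class fixes the
#' cross-tissue ratio exactly: exclusive genes are zero outside their
#' tissue (true tau 1), preferential genes have min/max = `ratio` (true
#' tau 1 - ratio), constitutive genes are equal in both tissues (true
#' tau 0).
#'
#' @param genes gene models with a `class` column (see [landscape_plan()]).
#' @param tissues two tissue labels, `c("root", "leaf")` order defines the
#'   matrix columns.
#' @param ratio min/max ratio of preferential genes.
#' @param seed integer seed.
#' @param base_meanlog,base_sdlog log-normal baseline parameters (defaults
#'   log(20) and 1, a realistic FPKM spread).
#' @return list with `expr` (matrix) and `truth` (data.table `gene_id`,
#'   `class`, `true_tau`).
#' @export
simulate_expression <- function(genes, tissues = c("root", "leaf"),
                                ratio = 0.005, seed = 1L,
                                base_meanlog = log(20), base_sdlog = 1) {
  stopifnot(ratio >= 0, ratio < 1, length(tissues) == 2L,
            "class" %in% names(genes))
  set.seed(.derive_seed(seed, "expression", 0L))
  base <- rlnorm(nrow(genes), base_meanlog, base_sdlog)
  minor <- function(cls) switch(cls,
    root_exclusive = , leaf_exclusive = 0,
    root_preferential = , leaf_preferential = ratio,
    constitutive = 1,
    stop("unknown expression class: ", cls))
  m <- vapply(genes$class, minor, 0)
  root_high <- genes$class %in% c("root_exclusive", "root_preferential",
                                  "constitutive")
  expr <- cbind(ifelse(root_high, base, base * m),
                ifelse(root_high, base * m, base))
  dimnames(expr) <- list(genes$gene_id, tissues)
  truth <- data.table(gene_id = genes$gene_id, class = genes$class,
                      true_tau = 1 - m)
  truth[class == "constitutive", true_tau := 0]
  list(expr = expr, truth = truth)
}

#' Assemble the ground-truth manifest of a simulated dataset
#'
#' @param plan a [landscape_plan()].
#' @param expr_truth per-gene truth from [simulate_expression()].
#' @return list of class `TruthManifest`: planted valleys, planted DMR
#'   windows, gene classes with true tau, compartment probabilities, seed.
#' @export
truth_manifest <- function(plan, expr_truth) {
  if (!is.null(plan$genes) &&
      !all(expr_truth$gene_id %in% plan$genes$gene_id))
    stop("manifest references gene(s) absent from the annotation")
  structure(list(
    valleys = plan$compartments[class == "valley",
                                .(chrom, start, end)],
    dmr_windows = plan$planted_dmr_windows,
    gene_classes = expr_truth,
    class_probs = plan$class_probs,
    seed = plan$seed), class = "TruthManifest")
}

#' Write / read a truth manifest as JSON
#'
#' @param manifest a [truth_manifest()].
#' @param path JSON path.
#' @export
write_truth <- function(manifest, path) {
  jsonlite::write_json(
    list(valleys = manifest$valleys, dmr_windows = manifest$dmr_windows,
         gene_classes = manifest$gene_classes,
         class_probs = list(classes = rownames(manifest$class_probs),
                            contexts = colnames(manifest$class_probs),
                            values = manifest$class_probs),
         seed = manifest$seed),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::fromJSON(path)
  probs <- matrix(unlist(x$class_probs$values),
                  nrow = length(x$class_probs$classes),
                  dimnames = list(x$class_probs$classes,
                                  x$class_probs$contexts))
  structure(list(valleys = as.data.table(x$valleys),
                 dmr_windows = as.data.table(x$dmr_windows),
                 gene_classes = as.data.table(x$gene_classes),
                 class_probs = probs, seed = x$seed),
            class = "TruthManifest")
}

#' Simulate a complete dataset from a landscape plan
#'
#' Genome + cytosine catalog, one methylome per tissue/replicate,
#' expression matrix and truth manifest; optionally written to disk as
#' FASTA, cytosine reports, BED annotation, expression TSV and truth JSON.
#'
#' @param plan a [landscape_plan()] with genes.
#' @param out_dir optional output directory (created if missing).
#' @return list with `fasta`, `catalog`, `samples` (list of
#'   [MethylomeSample] named `<tissue><rep>`), `genes`, `expr`, `truth`,
#'   `plan`.
#' @export
simulate_dataset <- function(plan = default_landscape_plan(),
                             out_dir = NULL) {
  if (is.null(plan$genes)) stop("plan carries no gene models")
  g <- simulate_genome(plan)
  samples <- list()
  for (ts in plan$tissues)
    for (r in seq_len(plan$n_replicates))
      samples[[paste0(ts, r)]] <- sample_methylome(plan, g$catalog, ts, r)
  ex <- simulate_expression(plan$genes, plan$tissues[1:2],
                            plan$preferential_ratio, plan$seed)
  truth <- truth_manifest(plan, ex$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genome_fasta(g$fasta, file.path(out_dir, "genome.fa"))
    for (nm in names(samples))
      write_cytosine_report(samples[[nm]],
                            file.path(out_dir, paste0(nm, ".cx.txt")))
    write_intervals_bed(
      plan$genes[, .(chrom, start, end, name = gene_id, score = 0, strand)],
      file.path(out_dir, "genes.bed"),
      chrom_order = names(plan$chrom_sizes))
    fwrite(data.table(gene_id = rownames(ex$expr), ex$expr),
           file.path(out_dir, "expression.tsv"), sep = "\t")
    write_truth(truth, file.path(out_dir, "truth.json"))
  }
  list(fasta = g$fasta, catalog = g$catalog, samples = samples,
       genes = plan$genes, expr = ex$expr, truth = truth, plan = plan)
}
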