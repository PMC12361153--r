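#' Pipeline configuration
#'
#' Collects every input and threshold of the end-to-end analysis in one
#' object so that a run is a pure function of (config, seed). Inputs may be
#' file paths (cytosine reports, BED/GFF3 annotation, expression TSV) or
#' the in-memory objects the rest of the package uses.
#'
#' @param samples either a data.frame sample sheet with columns `path`,
#'   `sample_id`, `tissue`, `replicate`, or a named list of
#'   [MethylomeSample] (exactly two tissues).
#' @param chrom_sizes named chromosome lengths (required with a sample
#'   sheet).
#' @param annotation gene annotation path (BED6/GFF3) or gene model
#'   data.table.
#' @param expression expression table path or gene x tissue matrix.
#' @param out_dir output directory, or `NULL` for an in-memory run.
#' @param dmr_contexts contexts to call DMRs in (default CG, CHG, CHH).
#' @param dmr_overrides optional named list `context -> dmr_criteria()`
#'   replacing the per-context defaults.
#' @param dmv a [dmv_params()] object.
#' @param tau_min,min_max_abundance preferential-gene thresholds (defaults
#'   0.99 and 1 FPKM).
#' @param constitutive_tau_max genes with defined tau at or below this are
#'   the "constitutive" metagene reference set (default 0.5).
#' @param fold_cutoff two-group fold-change cutoff (default 2).
#' @param flank flank width for DMR-gene association and metagene profiles
#'   (default 2000).
#' @param universe enrichment universe: `"expressed"` (genes with defined
#'   tau) or `"annotated"` (all genes).
#' @param seed integer seed stamped into the report (the pipeline itself is
#'   deterministic given its inputs).
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(samples, chrom_sizes = NULL, annotation,
                            expression, out_dir = NULL,
                            dmr_contexts = c("CG", "CHG", "CHH"),
                            dmr_overrides = NULL, dmv = dmv_params(),
                            tau_min = 0.99, min_max_abundance = 1,
                            constitutive_tau_max = 0.5, fold_cutoff = 2,
                            flank = 2000L,
                            universe = c("expressed", "annotated"),
                            seed = 1L) {
  universe <- match.arg(universe)
  structure(list(samples = samples, chrom_sizes = chrom_sizes,
                 annotation = annotation, expression = expression,
                 out_dir = out_dir, dmr_contexts = dmr_contexts,
                 dmr_overrides = dmr_overrides, dmv = dmv,
                 tau_min = tau_min, min_max_abundance = min_max_abundance,
                 constitutive_tau_max = constitutive_tau_max,
                 fold_cutoff = fold_cutoff, flank = as.integer(flank),
                 universe = universe, seed = as.integer(seed)),
            class = "PipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.load_pipeline_samples <- function(config) {
  if (is.data.frame(config$samples)) {
    sheet <- as.data.table(config$samples)
    stopifnot(all(c("path", "sample_id", "tissue", "replicate") %in%
                    names(sheet)), !is.null(config$chrom_sizes))
    miss <- sheet$path[!file.exists(sheet$path)]
    if (length(miss)) stop("sample file not found: ", miss[1L])
    samples <- lapply(seq_len(nrow(sheet)), function(i)
      read_cytosine_report(sheet$path[i], sheet$sample_id[i],
                           sheet$tissue[i], sheet$replicate[i],
                           config$chrom_sizes))
    names(samples) <- sheet$sample_id
    samples
  } else config$samples
}

#' Run the full methylome analysis pipeline
#'
#' Executes, in order: per-sample global methylation summaries; per-context
#' DMR calling between the two tissues (replicates pooled inside the
#' caller) with DMR-gene association; per-tissue DMV detection on
#' replicate-pooled methylomes with DMV-gene classification and the
#' cross-tissue overlap; tau specificity and tissue-preferential gene
#' sets plus the 2-fold classification; hypergeometric enrichment of each
#' tissue's preferential genes in its DMV genes; and metagene profiles of
#' preferential versus constitutive genes per tissue. When `out_dir` is
#' set, every stage writes its TSV/BED outputs there and the summary is
#' stamped with the configuration hash and seed.
#'
#' @param config a [pipeline_config()].
#' @return list with per-stage results and a `summary` list (per-tissue
#'   DMV region/gene counts, shared DMV genes, per-context DMR counts,
#'   preferential gene counts, preferential-in-DMV overlap counts and
#'   percentages, enrichment p-values, config hash, seed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  samples <- .stage("load_samples", .load_pipeline_samples(config))
  tissues <- unique(vapply(samples, `[[`, "", "tissue"))
  if (length(tissues) != 2L)
    stop("pipeline expects exactly 2 tissues, got ",
         length(tissues))
  genes <- .stage("load_annotation",
                  if (is.character(config$annotation))
                    read_gene_annotation(config$annotation)
                  else as.data.table(config$annotation))
  expr <- .stage("load_expression",
                 if (is.character(config$expression)) {
                   if (!file.exists(config$expression))
                     stop("expression table not found: ", config$expression)
                   read_expression_table(config$expression)
                 } else config$expression)
  if (!all(tissues %in% colnames(expr)))
    stop("sample tissue(s) absent from expression columns: ",
         paste(setdiff(tissues, colnames(expr)), collapse = ", "))
  chrom_sizes <- samples[[1L]]$chrom_sizes
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)

  globals <- .stage("global_stats", lapply(samples, function(s) {
    gs <- global_methylation_summary(s)
    data.table(sample_id = s$sample_id, tissue = s$tissue,
               context = names(gs$levels), level = gs$levels,
               mC_count = c(gs$mC_counts, NA),
               mC_proportion = c(gs$proportions, NA))
  }))
  globals <- rbindlist(globals)

  by_tissue <- split(samples, vapply(samples, `[[`, "", "tissue"))
  group_a <- by_tissue[[tissues[1L]]]
  group_b <- by_tissue[[tissues[2L]]]
  dmrs <- .stage("dmr", {
    res <- lapply(setNames(nm = config$dmr_contexts), function(cx) {
      crit <- config$dmr_overrides[[cx]] %||% dmr_criteria(cx)
      call_dmrs(group_a, group_b, crit)
    })
    res
  })
  dmr_genes <- .stage("dmr_genes", {
    all_dmrs <- rbindlist(dmrs)
    dmr_associated_genes(all_dmrs, genes, chrom_sizes, config$flank)
  })

  pooled <- .stage("pool", lapply(by_tissue, pool_samples))
  dmvs <- .stage("dmv", lapply(pooled, detect_dmvs, params = config$dmv))
  dmv_gene_sets <- .stage("dmv_genes", lapply(dmvs, dmv_genes,
                                              genes = genes,
                                              gene_fraction =
                                                config$dmv$gene_fraction))
  dmv_overlap <- .stage("dmv_overlap", dmv_tissue_overlap(dmv_gene_sets))

  tt <- .stage("tau", tau_table(expr))
  pref <- .stage("preferential",
                 preferential_genes(expr, config$tau_min,
                                    config$min_max_abundance))
  de <- .stage("fold_change",
               fold_change_de(expr, colnames(expr)[1L], colnames(expr)[2L],
                              config$fold_cutoff))

  universe <- if (config$universe == "expressed")
    tt$gene_id[!is.na(tt$tau)] else genes$gene_id
  enrich <- .stage("enrichment", lapply(setNames(nm = tissues), function(ts) {
    pg <- intersect(pref[[ts]] %||% character(), universe)
    dg <- intersect(dmv_gene_sets[[ts]], universe)
    set_enrichment(dg, pg, universe)
  }))

  constitutive <- tt$gene_id[!is.na(tt$tau) &
                             tt$tau <= config$constitutive_tau_max &
                             tt$max_value >= config$min_max_abundance]
  profiles <- .stage("metagene", lapply(setNames(nm = tissues), function(ts) {
    sets <- list(preferential = genes[gene_id %in% (pref[[ts]] %||%
                                                      character())],
                 constitutive = genes[gene_id %in% constitutive])
    lapply(sets, function(g)
      if (nrow(g)) metagene_profile(pooled[[ts]], g, flank = config$flank)
      else NULL)
  }))

  pref_counts <- vapply(tissues, function(ts)
    length(pref[[ts]] %||% character()), 0L)
  overlap_counts <- vapply(tissues, function(ts)
    length(intersect(pref[[ts]] %||% character(), dmv_gene_sets[[ts]])), 0L)
  summary <- list(
    tissues = tissues,
    dmv_regions = vapply(dmvs, nrow, 0L),
    dmv_genes = vapply(dmv_gene_sets, length, 0L),
    dmv_genes_shared = dmv_overlap$intersection,
    dmr_counts = vapply(dmrs, nrow, 0L),
    dmr_associated_genes = length(dmr_genes),
    preferential_genes = setNames(pref_counts, tissues),
    preferential_total = sum(pref_counts),
    preferential_in_dmv = setNames(overlap_counts, tissues),
    preferential_in_dmv_pct =
      setNames(ifelse(pref_counts > 0,
                      100 * overlap_counts / pref_counts, NA_real_),
               tissues),
    enrichment_p = vapply(enrich, `[[`, 0, "p_value"),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seed = config$seed)

  if (!is.null(out)) {
    fwrite(globals, file.path(out, "global_stats.tsv"), sep = "\t")
    for (cx in names(dmrs)) {
      fwrite(dmrs[[cx]], file.path(out, paste0("dmrs_", cx, ".tsv")),
             sep = "\t")
      write_intervals_bed(dmrs[[cx]],
                          file.path(out, paste0("dmrs_", cx, ".bed")),
                          chrom_order = names(chrom_sizes))
    }
    writeLines(dmr_genes, file.path(out, "dmr_associated_genes.txt"))
    for (ts in tissues) {
      write_intervals_bed(dmvs[[ts]],
                          file.path(out, paste0("dmv_", ts, ".bed")),
                          chrom_order = names(chrom_sizes))
      writeLines(dmv_gene_sets[[ts]],
                 file.path(out, paste0("dmv_genes_", ts, ".txt")))
      writeLines(pref[[ts]] %||% character(),
                 file.path(out, paste0("preferential_", ts, ".txt")))
      for (set in names(profiles[[ts]]))
        if (!is.null(profiles[[ts]][[set]]))
          fwrite(metagene_table(profiles[[ts]][[set]]),
                 file.path(out, sprintf("metagene_%s_%s.tsv", ts, set)),
                 sep = "\t")
    }
    fwrite(tt, file.path(out, "tau.tsv"), sep = "\t")
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(samples = samples, globals = globals, dmrs = dmrs,
       dmr_genes = dmr_genes, dmvs = dmvs, dmv_gene_sets = dmv_gene_sets,
       dmv_overlap = dmv_overlap, tau = tt, preferential = pref,
       fold_change = de, enrichment = enrich, profiles = profiles,
       summary = summary)
}
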