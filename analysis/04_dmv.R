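#!/usr/bin/env Rscript
# Stage 4: DNA methylation valleys per tissue.
#
# Replicates are pooled by summing counts per site; the pooled methylome is
# scanned in 1 kb windows at 200 bp steps, windows with mean per-site level
# < 5% (all contexts, coverage >= 4, >= 5 sites) are merged into valleys.
# Genes with >= 80% of their body in the valley union are DMV genes.

suppressMessages({library(methvalley); library(data.table)})

sim_dir <- "results/sim"
plan <- default_landscape_plan(seed = 1L)
genes <- read_gene_annotation(file.path(sim_dir, "genes.bed"))
truth <- read_truth(file.path(sim_dir, "truth.json"))

gene_sets <- list()
for (ts in c("root", "leaf")) {
  grp <- lapply(1:3, function(r)
    read_cytosine_report(file.path(sim_dir, sprintf("%s%d.cx.txt", ts, r)),
                         paste0(ts, r), ts, r, plan$chrom_sizes))
  pooled <- pool_samples(grp)
  dmvs <- detect_dmvs(pooled)
  write_intervals_bed(dmvs, sprintf("results/dmv_%s.bed", ts),
                      chrom_order = names(plan$chrom_sizes))
  gene_sets[[ts]] <- dmv_genes(dmvs, genes)
  writeLines(gene_sets[[ts]], sprintf("results/dmv_genes_%s.txt", ts))
  jac <- vapply(seq_len(nrow(truth$valleys)), function(i) {
    tv <- truth$valleys[i]
    ov <- dmvs[chrom == tv$chrom & start < tv$end & end > tv$start]
    if (!nrow(ov)) return(0)
    inter <- sum(pmin(ov$end, tv$end) - pmax(ov$start, tv$start))
    inter / (sum(ov$end - ov$start) + tv$end - tv$start - inter)
  }, 0)
  cat(sprintf("%s: %d valley regions, %d DMV genes; planted-valley Jaccard min %.3f median %.3f\n",
              ts, nrow(dmvs), length(gene_sets[[ts]]), min(jac), median(jac)))
}

ov <- dmv_tissue_overlap(gene_sets)
cat(sprintf("DMV genes shared root/leaf: %d of %d (union); Jaccard %.3f\n",
            ov$intersection, ov$union, ov$intersection / ov$union))
writeLines(ov$shared_genes, "results/dmv_genes_shared.txt")
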