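#!/usr/bin/env Rscript
# Stage 3: differential methylation between root and leaf.
#
# 200 bp windows, per-base coverage >= 4, pooled replicate counts, Pearson
# chi-square with BH adjustment; per-context criteria CG 5/0.25, CHG
# 5/0.25, CHH 15/0.15, all-C 20/0.20, all at q <= 0.05. DMR-associated
# genes are those whose 2 kb-flanked bodies touch any DMR.

suppressMessages({library(methvalley); library(data.table)})

sim_dir <- "results/sim"
plan <- default_landscape_plan(seed = 1L)
load_grp <- function(ts) lapply(1:3, function(r)
  read_cytosine_report(file.path(sim_dir, sprintf("%s%d.cx.txt", ts, r)),
                       paste0(ts, r), ts, r, plan$chrom_sizes))
root <- load_grp("root"); leaf <- load_grp("leaf")

for (cx in c("CG", "CHG", "CHH", "ALL_C")) {
  dmrs <- call_dmrs(root, leaf, dmr_criteria(cx))
  fwrite(dmrs, sprintf("results/dmrs_%s.tsv", cx), sep = "\t")
  cat(sprintf("%-6s: %4d DMRs from %d tested windows (%d degenerate skipped)\n",
              cx, nrow(dmrs), attr(dmrs, "n_tested"),
              attr(dmrs, "n_skipped")))
}

dmrs_cg <- fread("results/dmrs_CG.tsv")
genes <- read_gene_annotation(file.path(sim_dir, "genes.bed"))
assoc <- dmr_associated_genes(dmrs_cg, genes, plan$chrom_sizes)
writeLines(assoc, "results/dmr_associated_genes.txt")
cat(sprintf("CG DMR-associated genes (2 kb flank rule): %d\n", length(assoc)))

truth <- read_truth(file.path(sim_dir, "truth.json"))
hit <- paste(truth$dmr_windows$chrom, truth$dmr_windows$start) %in%
  paste(dmrs_cg$chrom, dmrs_cg$start)
cat(sprintf("planted CG windows recovered: %d/%d (sensitivity %.2f)\n",
            sum(hit), length(hit), mean(hit)))
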