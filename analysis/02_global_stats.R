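#!/usr/bin/env Rscript
# Stage 2: genome-wide methylation overview.
#
# Per sample: read-weighted methylation level per context, methylcytosine
# calls (binomial test vs the 0.5% error rate, BH q <= 0.05 at coverage
# >= 4) and their context proportions; plus 100 kb window tracks of the
# replicate-pooled tissues for browser-style inspection.

suppressMessages({library(methvalley); library(data.table)})

sim_dir <- "results/sim"
plan <- default_landscape_plan(seed = 1L)
ids <- c(paste0("root", 1:3), paste0("leaf", 1:3))
samples <- lapply(ids, function(id)
  read_cytosine_report(file.path(sim_dir, paste0(id, ".cx.txt")), id,
                       sub("[0-9]+$", "", id),
                       as.integer(sub("^[a-z]+", "", id)),
                       plan$chrom_sizes))
names(samples) <- ids

summ <- rbindlist(lapply(samples, function(s) {
  gs <- global_methylation_summary(s)
  data.table(sample_id = s$sample_id, tissue = s$tissue,
             context = names(gs$levels), weighted_level = gs$levels,
             mC_count = c(gs$mC_counts, NA),
             mC_proportion = c(gs$proportions, NA))
}))
dir.create("results", showWarnings = FALSE)
fwrite(summ, "results/global_stats.tsv", sep = "\t")

cat("per-sample weighted levels (CG):\n")
print(summ[context == "CG", .(sample_id, weighted_level = round(weighted_level, 4))])
cat("\nmC context proportions, root1:\n")
print(summ[sample_id == "root1" & context != "ALL",
           .(context, round(mC_proportion, 4))])

genes <- read_gene_annotation(file.path(sim_dir, "genes.bed"))
for (ts in c("root", "leaf")) {
  pooled <- pool_samples(samples[grep(ts, ids)])
  win <- chromosome_window_summary(pooled, window_size = 100000L,
                                   genes = genes)
  fwrite(win, sprintf("results/windows_100kb_%s.tsv", ts), sep = "\t")
}
cat("\nwrote results/global_stats.tsv and 100 kb window tracks\n")
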