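#!/usr/bin/env Rscript
# Stage 1: generate the synthetic WGBS study.
#
# Builds the default landscape — 3 x 200 kb chromosomes carrying TE-like
# hypermethylated blocks, a moderately methylated gene region, planted 3 kb
# methylation valleys and planted CG-differential windows — then simulates
# two tissues (root, leaf) x three replicates at 10x coverage, plus the
# gene annotation, expression matrix and ground-truth manifest.

suppressMessages(library(methvalley))

out <- "results/sim"
plan <- default_landscape_plan(seed = 1L)
sim <- simulate_dataset(plan, out_dir = out)

cat(sprintf("genome: %d chromosomes, %s bp, %s cytosine sites\n",
            length(plan$chrom_sizes),
            format(sum(plan$chrom_sizes), big.mark = ","),
            format(nrow(sim$catalog), big.mark = ",")))
cat(sprintf("samples: %s\n", paste(names(sim$samples), collapse = ", ")))
cat(sprintf("planted: %d valleys, %d CG-differential windows, %d genes\n",
            nrow(sim$truth$valleys), nrow(sim$truth$dmr_windows),
            nrow(sim$genes)))
cat("written to", out, "\n")
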