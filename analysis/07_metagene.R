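#!/usr/bin/env Rscript
# Stage 7: metagene methylation profiles around TSS/TES.
#
# Strand-aware profiles (2 kb flanks in 20 bins each, gene body scaled to
# 60 bins) of root-preferential versus constitutive genes on the pooled
# root methylome, per context. The planted design has valley-resident
# preferential genes, so their CG gene-body methylation should sit far
# below the constitutive genes'.

suppressMessages({library(methvalley); library(data.table)})

sim_dir <- "results/sim"
plan <- default_landscape_plan(seed = 1L)
genes <- read_gene_annotation(file.path(sim_dir, "genes.bed"))
tt <- fread("results/tau.tsv")

pooled <- pool_samples(lapply(1:3, function(r)
  read_cytosine_report(file.path(sim_dir, sprintf("root%d.cx.txt", r)),
                       paste0("root", r), "root", r, plan$chrom_sizes)))

pref_ids <- readLines("results/preferential_root.txt")
cons_ids <- tt[!is.na(tau) & tau <= 0.5 & max_value >= 1]$gene_id
sets <- list(preferential = genes[gene_id %in% pref_ids],
             constitutive = genes[gene_id %in% cons_ids])

profiles <- lapply(sets, function(g) metagene_profile(pooled, g))
for (nm in names(profiles))
  fwrite(metagene_table(profiles[[nm]]),
         sprintf("results/metagene_root_%s.tsv", nm), sep = "\t")

body <- 21:80
for (cx in c("C", "CG", "CHG", "CHH")) {
  mp <- mean(profiles$preferential$levels[cx, body], na.rm = TRUE)
  mc <- mean(profiles$constitutive$levels[cx, body], na.rm = TRUE)
  cat(sprintf("%-3s gene-body mean level: preferential %.3f vs constitutive %.3f\n",
              cx, mp, mc))
}
frac <- mean(profiles$preferential$levels["CG", body] <
               profiles$constitutive$levels["CG", body], na.rm = TRUE)
cat(sprintf("CG body bins where preferential < constitutive: %.0f%%\n",
            100 * frac))
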