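#!/usr/bin/env Rscript
# Stage 5: tissue specificity of expression.
#
# tau index per gene on the FPKM-like matrix (two tissues: tau = 1 -
# min/max); genes with tau >= 0.99 and max abundance >= 1 are
# tissue-preferential, assigned to their top tissue. The plain 2-fold
# classification is reported alongside.

suppressMessages({library(methvalley); library(data.table)})

expr <- read_expression_table("results/sim/expression.tsv")
tt <- tau_table(expr)
fwrite(tt, "results/tau.tsv", sep = "\t")

pref <- preferential_genes(expr, tau_min = 0.99, min_max_abundance = 1)
for (ts in names(pref))
  writeLines(pref[[ts]], sprintf("results/preferential_%s.txt", ts))
de <- fold_change_de(expr, "root", "leaf", cutoff = 2)

cat(sprintf("genes: %d; defined tau: %d\n", nrow(tt), sum(!is.na(tt$tau))))
cat(sprintf("tissue-preferential (tau >= 0.99, max >= 1): root %d, leaf %d, total %d\n",
            length(pref$root), length(pref$leaf),
            length(pref$root) + length(pref$leaf)))
cat(sprintf("2-fold classification: up in root %d, up in leaf %d\n",
            length(de$up_in_a), length(de$up_in_b)))

truth <- read_truth("results/sim/truth.json")
planted <- truth$gene_classes[true_tau >= 0.99]$gene_id
recovered <- sort(c(pref$root, pref$leaf))
cat(sprintf("planted high-tau genes recovered: %d/%d\n",
            length(intersect(recovered, planted)), length(planted)))
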