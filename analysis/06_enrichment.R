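#!/usr/bin/env Rscript
# Stage 6: are tissue-preferential genes over-represented among DMV genes?
#
# Hypergeometric upper-tail test of the overlap between each tissue's
# preferential gene set and its DMV gene set, against the universe of
# genes with defined tau (expressed somewhere).

suppressMessages({library(methvalley); library(data.table)})

tt <- fread("results/tau.tsv")
universe <- tt[!is.na(tau)]$gene_id

rows <- list()
for (ts in c("root", "leaf")) {
  pref <- readLines(sprintf("results/preferential_%s.txt", ts))
  dmv <- intersect(readLines(sprintf("results/dmv_genes_%s.txt", ts)),
                   universe)
  res <- set_enrichment(dmv, pref, universe)
  rows[[ts]] <- data.table(tissue = ts, universe = res$N, dmv = res$K,
                           preferential = res$n, overlap = res$k,
                           pct_pref_in_dmv = round(100 * res$k / max(1, res$n), 1),
                           fold_enrichment = round(res$fold_enrichment, 2),
                           p_value = res$p_value)
  cat(sprintf("%s: %d/%d preferential genes are DMV genes (%.1f%%), fold %.2f, hypergeometric p = %.3g\n",
              ts, res$k, res$n, 100 * res$k / max(1, res$n),
              res$fold_enrichment, res$p_value))
}
fwrite(rbindlist(rows), "results/enrichment.tsv", sep = "\t")
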