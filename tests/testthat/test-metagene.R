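# independent per-gene binning oracle: plain loops over genes and sites
oracle_metagene <- function(sample, genes, flank = 2000L, U = 20L, B = 60L,
                            D = 20L) {
  nbins <- U + B + D
  meth <- total <- matrix(0, 4, nbins,
                          dimnames = list(c("C", "CG", "CHG", "CHH"), NULL))
  ubw <- flank %/% U; dbw <- flank %/% D
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    len <- g$end - g$start
    for (si in seq_len(nrow(sample$sites))) {
      st <- sample$sites[si, ]
      if (st$chrom != g$chrom) next
      p0 <- st$pos - 1L
      if (p0 < g$start - flank || p0 >= g$end + flank) next
      if (p0 >= g$start && p0 < g$end) {
        b5 <- min(((p0 - g$start) * B) %/% len, B - 1)
        bin <- if (g$strand == "+") U + b5 else U + (B - 1 - b5)
      } else if (p0 < g$start) {
        bin <- if (g$strand == "+") (p0 - (g$start - flank)) %/% ubw
               else U + B + (g$start - 1 - p0) %/% dbw
      } else {
        bin <- if (g$strand == "+") U + B + (p0 - g$end) %/% dbw
               else (g$end + flank - 1 - p0) %/% ubw
      }
      meth[st$context, bin + 1] <- meth[st$context, bin + 1] + st$meth
      total[st$context, bin + 1] <- total[st$context, bin + 1] +
        st$meth + st$unmeth
    }
  }
  meth["C", ] <- colSums(meth[2:4, ]); total["C", ] <- colSums(total[2:4, ])
  lv <- meth / total; lv[total == 0] <- NA_real_
  lv
}

test_that("a uniform methylome gives a flat profile at the planted level", {
  s <- make_uniform_sample(chrom_len = 20000L, spacing = 15L, level = 0.5)
  genes <- data.table(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(4000L, 12000L), end = c(6000L, 15000L),
                      strand = c("+", "-"))
  p <- metagene_profile(s, genes)
  expect_true(all(abs(p$levels - 0.5) < 1e-12, na.rm = TRUE))
  expect_equal(p$n_genes, 2L)
})

test_that("body/flank contrast matches the per-gene binning oracle", {
  # unmethylated gene bodies, 80%-methylated flanks
  set.seed(31)
  chrom_len <- 16000L
  pos <- sort(sample(seq(5L, chrom_len - 5L), 900L))
  genes <- data.table(gene_id = c("gp", "gm"), chrom = "chr1",
                      start = c(4000L, 10000L), end = c(6000L, 12400L),
                      strand = c("+", "-"))
  in_body <- (pos > genes$start[1] & pos <= genes$end[1]) |
             (pos > genes$start[2] & pos <= genes$end[2])
  lev <- ifelse(in_body, 0, 0.8)
  cov <- rpois(900L, 10) + 1L
  meth <- rbinom(900L, cov, lev)
  s <- make_sample(pos, meth, cov - meth,
                   context = sample(c("CG", "CHG", "CHH"), 900L, TRUE),
                   strand = sample(c("+", "-"), 900L, TRUE),
                   chrom_len = chrom_len)
  p <- metagene_profile(s, genes)
  expect_equal(p$levels, oracle_metagene(s, genes))
  body <- 21:80
  expect_true(all(p$levels["C", body] < 0.05, na.rm = TRUE))
  expect_gt(mean(p$levels["C", -body], na.rm = TRUE), 0.6)
})

test_that("minus-strand orientation puts 3'-flank signal downstream", {
  # gene on the minus strand; methylation only left of the gene start,
  # which is its 3' side -> downstream bins only
  pos <- seq(2005L, 3995L, by = 10L)
  s <- make_sample(pos, rep(8L, length(pos)), rep(2L, length(pos)),
                   chrom_len = 10000L)
  gene <- data.table(gene_id = "gm", chrom = "chr1", start = 4000L,
                     end = 6000L, strand = "-")
  p <- metagene_profile(s, gene)
  up <- 1:20; down <- 81:100
  expect_true(all(is.na(p$levels["CG", up])))
  expect_true(all(p$levels["CG", down] == 0.8))
})

test_that("profiles pool by read weight and reverse with strand flips", {
  s <- make_uniform_sample(chrom_len = 40000L, spacing = 11L, level = 0.3)
  set.seed(8)
  # make levels heterogeneous so pooling is a real test
  s$sites[, meth := rbinom(.N, meth + unmeth, runif(.N))]
  s$sites[, unmeth := 10L - meth]
  g1 <- data.table(gene_id = "a", chrom = "chr1", start = 5000L,
                   end = 8000L, strand = "+")
  g2 <- data.table(gene_id = "b", chrom = "chr1", start = 20000L,
                   end = 26000L, strand = "-")
  both <- rbind(g1, g2)
  p1 <- metagene_profile(s, g1); p2 <- metagene_profile(s, g2)
  pu <- metagene_profile(s, both)
  expect_equal(pu$meth, p1$meth + p2$meth)
  expect_equal(pu$total, p1$total + p2$total)

  flipped <- copy(both)[, strand := ifelse(strand == "+", "-", "+")]
  pf <- metagene_profile(s, flipped)
  expect_equal(pf$levels, pu$levels[, ncol(pu$levels):1],
               ignore_attr = TRUE)

  short <- data.table(gene_id = "tiny", chrom = "chr1", start = 100L,
                      end = 130L, strand = "+")
  expect_warning(metagene_profile(s, rbind(both, short)), "skipped")
})

test_that("planted gene-body hypomethylation shows in the CG body bins", {
  sim <- get_demo_sim()
  root <- get_demo_pooled("root")
  pref <- sim$genes[class == "root_exclusive"]
  cons <- sim$genes[class == "constitutive"]
  pp <- metagene_profile(root, pref)
  pc <- metagene_profile(root, cons)
  body <- 21:80
  frac_lower <- mean(pp$levels["CG", body] < pc$levels["CG", body],
                     na.rm = TRUE)
  expect_gte(frac_lower, 0.9)
})
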