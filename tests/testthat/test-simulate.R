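test_that("cytosine contexts follow the trinucleotide rule on both strands", {
  # the context rule is checked directly on hand-built sequences
  catalog_of <- function(seq_chars) methvalley:::.catalog_chrom(seq_chars, "c1")
  ct <- catalog_of(c("A", "C", "G", "T", "T"))
  expect_equal(ct[strand == "+" & pos == 2]$context, "CG")
  ct2 <- catalog_of(c("A", "C", "A", "G", "T"))
  expect_equal(ct2[strand == "+" & pos == 2]$context, "CHG")
  ct3 <- catalog_of(c("A", "C", "A", "A", "T"))
  expect_equal(ct3[strand == "+" & pos == 2]$context, "CHH")
  # minus strand: G at pos 4 preceded by C-A reads C..T-G on minus = CHG?
  # complement of (pos-1, pos-2) = (T->A? ) checked explicitly:
  # plus "ACAGT": G at 4; minus strand C at 4, next bases complement of
  # pos 3 (A->T) then pos 2 (C->G): C-T-G -> CHG
  expect_equal(ct2[strand == "-" & pos == 4]$context, "CHG")
  # plus "ACGTT": G at 3; minus C at 3, next = complement(C) = G -> CG
  expect_equal(ct[strand == "-" & pos == 3]$context, "CG")
})

test_that("catalog agrees with an independent re-derivation from the FASTA", {
  sim <- get_demo_sim()
  bases <- strsplit(sim$fasta[["chr2"]], "")[[1]]
  cat2 <- sim$catalog[chrom == "chr2"]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(44)
  idx <- sample(nrow(cat2), 500L)
  for (i in idx) {
    row <- cat2[i]
    tri <- if (row$strand == "+") bases[row$pos + 0:2]
           else comp[bases[row$pos - 0:2]]
    expect_equal(unname(tri[1]), "C")
    want <- if (tri[2] == "G") "CG" else if (tri[3] == "G") "CHG" else "CHH"
    expect_equal(row$context, want)
  }
  # completeness: every eligible C/G position is catalogued
  n_plus <- sum(bases == "C" & seq_along(bases) <= length(bases) - 2)
  n_minus <- sum(bases == "G" & seq_along(bases) >= 3)
  expect_equal(nrow(cat2), n_plus + n_minus)
})

test_that("identical seed and plan give byte-identical outputs", {
  plan <- default_landscape_plan(seed = 5L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- simulate_genome(plan); g2 <- simulate_genome(plan)
  expect_identical(g1$fasta, g2$fasta)
  s1 <- sample_methylome(plan, g1$catalog, "root", 1L,
                         file.path(d1, "r1.cx"))
  s2 <- sample_methylome(plan, g2$catalog, "root", 1L,
                         file.path(d2, "r1.cx"))
  expect_identical(readLines(file.path(d1, "r1.cx")),
                   readLines(file.path(d2, "r1.cx")))
  # a different replicate uses a different stream
  s3 <- sample_methylome(plan, g1$catalog, "root", 2L)
  expect_false(identical(s1$sites$meth, s3$sites$meth))
})

test_that("degenerate methylation probabilities behave deterministically", {
  probs <- rbind(background = c(0, 0, 0), hot = c(1, 1, 1))
  colnames(probs) <- c("CG", "CHG", "CHH")
  plan <- landscape_plan(c(c1 = 4000L),
                         data.table(chrom = "c1", start = 2000L,
                                    end = 4000L, class = "hot"),
                         probs, seed = 3L)
  g <- simulate_genome(plan)
  s <- sample_methylome(plan, g$catalog, "root", 1L)
  cold <- s$sites[pos <= 2000]
  hot <- s$sites[pos > 2000]
  expect_true(all(cold$meth == 0L))
  expect_true(all(hot$unmeth == 0L))
})

test_that("pooled simulated level sits within 3 SE of the planted mean", {
  probs <- rbind(background = c(0.5, 0.5, 0.5))
  colnames(probs) <- c("CG", "CHG", "CHH")
  plan <- landscape_plan(c(c1 = 30000L),
                         data.table(chrom = character(), start = integer(),
                                    end = integer(), class = character()),
                         probs, mean_coverage = 10, seed = 12L)
  g <- simulate_genome(plan)
  s <- sample_methylome(plan, g$catalog, "root", 1L)
  lv <- weighted_methylation_level(s)
  n_sites <- nrow(s$sites)
  reads <- sum(s$sites$meth + s$sites$unmeth)
  se <- sqrt(0.25 / reads + 0.25 / 51 / n_sites)
  expect_lt(abs(lv - 0.5), 3 * se)
})

test_that("expression classes fix the cross-tissue ratio exactly", {
  genes <- data.table(gene_id = paste0("g", 1:5), chrom = "c1",
                      start = (0:4) * 100L, end = (0:4) * 100L + 50L,
                      strand = "+",
                      class = c("root_exclusive", "leaf_exclusive",
                                "root_preferential", "leaf_preferential",
                                "constitutive"))
  ex <- simulate_expression(genes, ratio = 0.005, seed = 2L)
  expect_equal(unname(ex$expr["g1", "leaf"]), 0)
  expect_equal(ex$truth[gene_id == "g1"]$true_tau, 1)
  expect_equal(unname(ex$expr["g3", "leaf"] / ex$expr["g3", "root"]), 0.005)
  expect_equal(ex$truth[gene_id == "g3"]$true_tau, 0.995)
  expect_equal(unname(ex$expr["g5", "root"]), unname(ex$expr["g5", "leaf"]))
  expect_equal(ex$truth[gene_id == "g5"]$true_tau, 0)
  # realized tau matches the recorded truth
  for (gid in genes$gene_id)
    expect_equal(tau(ex$expr[gid, ]), ex$truth[gene_id == gid]$true_tau)
})

test_that("truth manifest round-trips through JSON and validates genes", {
  sim <- get_demo_sim()
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, f)
  back <- read_truth(f)
  expect_equal(back$valleys, sim$truth$valleys)
  expect_equal(back$gene_classes, sim$truth$gene_classes)
  expect_equal(back$class_probs, sim$truth$class_probs)
  expect_equal(back$seed, sim$truth$seed)

  bad <- copy(sim$truth$gene_classes)
  bad[1, gene_id := "ghost"]
  expect_error(truth_manifest(sim$plan, bad), "absent from the annotation")
})

test_that("simulate_dataset writes a complete, readable file set", {
  d <- withr::local_tempdir()
  plan <- default_landscape_plan(seed = 2L)
  plan$chrom_sizes <- plan$chrom_sizes[1L]  # one chromosome for speed
  plan$compartments <- plan$compartments[chrom == "chr1"]
  plan$planted_dmr_windows <- plan$planted_dmr_windows[chrom == "chr1"]
  plan$genes <- plan$genes[chrom == "chr1"]
  sim <- simulate_dataset(plan, out_dir = d)
  expect_true(all(file.exists(file.path(
    d, c("genome.fa", "root1.cx.txt", "leaf3.cx.txt", "genes.bed",
         "expression.tsv", "truth.json")))))
  s <- read_cytosine_report(file.path(d, "root1.cx.txt"), "root1", "root",
                            1L, plan$chrom_sizes)
  expect_equal(s$sites, sim$samples$root1$sites)
  genes <- read_gene_annotation(file.path(d, "genes.bed"))
  expect_setequal(genes$gene_id, plan$genes$gene_id)
  expr <- read_expression_table(file.path(d, "expression.tsv"))
  expect_equal(expr, sim$expr)
})
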