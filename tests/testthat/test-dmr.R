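test_that("fixed tiling covers chromosomes including the partial tail", {
  tw <- tile_windows(c(chr1 = 500L), 200L)
  expect_equal(tw$start, c(0L, 200L, 400L))
  expect_equal(tw$end, c(200L, 400L, 500L))
  expect_equal(nrow(tile_windows(c(chr1 = 200L), 200L)), 1L)
  expect_equal(nrow(tile_windows(c(chr1 = 7L), 1L)), 7L)
})

test_that("window aggregation pools replicates and applies the coverage rule", {
  w <- list(chrom = "chr1", start = 0L, end = 200L)
  reps <- lapply(1:2, function(r)
    make_sample(pos = 50L, meth = 3L, unmeth = 1L, replicate = r))
  agg <- aggregate_window_counts(reps, w, "CG", min_site_cov = 4L)
  expect_equal(agg, list(n_sites = 1L, meth = 6L, total = 8L))

  low <- lapply(1:2, function(r)
    make_sample(pos = 50L, meth = 2L, unmeth = 1L, replicate = r))
  expect_equal(aggregate_window_counts(low, w, "CG", 4L)$n_sites, 0L)

  empty_w <- list(chrom = "chr1", start = 400L, end = 600L)
  expect_equal(aggregate_window_counts(reps, empty_w, "CG", 4L),
               list(n_sites = 0L, meth = 0L, total = 0L))

  # a site may qualify in one replicate only; ALL_C pools contexts
  mixed <- list(make_sample(pos = c(50L, 60L), meth = c(3L, 5L),
                            unmeth = c(1L, 0L), context = c("CG", "CHH")),
                make_sample(pos = 50L, meth = 2L, unmeth = 1L))
  expect_equal(aggregate_window_counts(mixed, w, "ALL_C", 4L),
               list(n_sites = 2L, meth = 8L, total = 9L))
})

test_that("Pearson chi-square matches hand computation and stats oracle", {
  expect_equal(chisq_2x2(50, 50, 50, 50), data.table(chi2 = 0, p = 1))
  # expected counts all 50 -> chi2 = 4 * 1600/50 = 128
  r <- chisq_2x2(90, 10, 10, 90)
  expect_equal(r$chi2, 128)
  expect_error(chisq_2x2(0, 10, 0, 10), "degenerate")
  expect_error(chisq_2x2(-1, 10, 5, 10), "negative")

  set.seed(3)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 40) + 1L, 2L)
    ours <- chisq_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("chi-square approximation tracks the exact conditional test", {
  # exact p: probability, over all 2x2 tables with the observed margins,
  # of a chi-square statistic at least as large (= two-sided Fisher)
  exact_p <- function(ma, ua, mb, ub) {
    ra <- ma + ua; rb <- mb + ub; cm <- ma + mb
    a <- max(0, cm - rb):min(ra, cm)
    chi2 <- vapply(a, function(x)
      chisq_2x2(x, ra - x, cm - x, rb - cm + x)$chi2, 0)
    obs <- chisq_2x2(ma, ua, mb, ub)$chi2
    sum(stats::dhyper(a, ra, rb, cm)[chi2 >= obs - 1e-9])
  }
  # the continuous approximation of a discrete tail is good to a few units
  # of the largest point mass near the cutoff; that bound shrinks with the
  # table, so the same check is loose at 5 expected and tight at 100
  set.seed(5)
  checked <- 0L
  while (checked < 25L) {
    ma <- rpois(1, 30); ua <- rpois(1, 30)
    mb <- rpois(1, 30); ub <- rpois(1, 30)
    ra <- ma + ua; rb <- mb + ub; n <- ra + rb
    exp_min <- min(outer(c(ra, rb), c(ma + mb, ua + ub)) / n)
    if (exp_min < 5) next
    checked <- checked + 1L
    for (scale in c(1L, 20L)) {
      t <- scale * c(ma, ua, mb, ub)
      max_mass <- max(stats::dhyper(
        max(0, t[1] + t[3] - t[3] - t[4]):min(t[1] + t[2], t[1] + t[3]),
        t[1] + t[2], t[3] + t[4], t[1] + t[3]))
      expect_lt(abs(chisq_2x2(t[1], t[2], t[3], t[4])$p -
                      exact_p(t[1], t[2], t[3], t[4])),
                3 * max_mass + 0.005)
    }
  }
})

test_that("BH adjustment reproduces the step-up and matches p.adjust", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric()), numeric())
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  }
})

test_that("DMR calling recovers a planted window and respects thresholds", {
  # planted: 6 CG sites, group A pooled 90/100 methylated reads, B 10/100
  mk <- function(meth_per_site, id, tissue) {
    pos <- seq(10L, by = 30L, length.out = 6L)
    m <- as.integer(round(meth_per_site))
    make_sample(pos, rep(m, 6L), rep(17L - m, 6L), sample_id = id,
                tissue = tissue, chrom_len = 400L)
  }
  a <- list(mk(15, "a1", "root")); b <- list(mk(2, "b1", "leaf"))
  dmrs <- call_dmrs(a, b, dmr_criteria("CG"))
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$diff, (15 - 2) / 17)
  expect_equal(dmrs$n_sites_a, 6L)
  expect_true(dmrs$q <= 0.05)

  # identical groups: nothing called
  expect_equal(nrow(call_dmrs(a, a, dmr_criteria("CG"))), 0L)

  # 4 CG sites under the CG criteria (min 5): window not tested
  mk4 <- function(m, tissue) make_sample(seq(10L, by = 30L, length.out = 4L),
                                         rep(m, 4L), rep(17L - m, 4L),
                                         tissue = tissue, chrom_len = 400L)
  res4 <- call_dmrs(list(mk4(15L, "root")), list(mk4(2L, "leaf")),
                    dmr_criteria("CG"))
  expect_equal(attr(res4, "n_tested"), 0L)

  expect_error(call_dmrs(list(), a), "at least one sample")
})

test_that("every reported DMR satisfies its criteria simultaneously", {
  sim <- get_demo_sim()
  a <- sim$samples[paste0("root", 1:3)]
  b <- sim$samples[paste0("leaf", 1:3)]
  crit <- dmr_criteria("CG")
  dmrs <- call_dmrs(a, b, crit)
  expect_gt(nrow(dmrs), 0L)
  expect_true(all(dmrs$n_sites_a >= crit$min_sites &
                  dmrs$n_sites_b >= crit$min_sites))
  expect_true(all(abs(dmrs$diff) >= crit$min_abs_diff))
  expect_true(all(dmrs$q <= crit$q_max))
  expect_true(all(abs(dmrs$diff) <= 1))
  # q monotone non-decreasing in p across the tested family
  all_w <- call_dmrs(a, b, crit, return_all = TRUE)
  ord <- order(all_w$p)
  expect_true(all(diff(all_w$q[ord]) >= -1e-12))
})

test_that("degenerate windows are skipped, not assigned p = 1", {
  mk0 <- function(tissue) make_sample(seq(10L, by = 30L, length.out = 6L),
                                      rep(0L, 6L), rep(10L, 6L),
                                      tissue = tissue, chrom_len = 300L)
  res <- call_dmrs(list(mk0("root")), list(mk0("leaf")), dmr_criteria("CG"),
                   return_all = TRUE)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "n_skipped"), 1L)
  expect_equal(attr(res, "n_tested"), 0L)
})

test_that("DMR-gene association uses the 2 kb flank rule", {
  cs <- c(chr1 = 10000L)
  dmrs <- data.table(chrom = "chr1", start = 0L, end = 200L)
  genes <- data.table(gene_id = c("near", "far", "inside"),
                      chrom = "chr1",
                      start = c(1500L, 2300L, 100L),
                      end = c(3000L, 3000L, 150L),
                      strand = "+")
  expect_equal(dmr_associated_genes(dmrs, genes, cs),
               c("inside", "near"))
  expect_equal(dmr_associated_genes(dmrs, genes, cs, flank = 0L), "inside")
})
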