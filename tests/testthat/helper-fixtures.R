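library(data.table)

# small in-code methylome: sites given as a data.frame-like list of vectors
make_sample <- function(pos, meth, unmeth, context = "CG", strand = "+",
                        chrom = "chr1", chrom_len = max(pos) + 100L,
                        sample_id = "s1", tissue = "root", replicate = 1L) {
  n <- length(pos)
  MethylomeSample(sample_id, tissue, replicate,
                  data.table(chrom = rep_len(chrom, n), pos = pos,
                             strand = rep_len(strand, n),
                             context = rep_len(context, n),
                             meth = meth, unmeth = unmeth),
                  setNames(chrom_len, chrom[1L]))
}

# dense uniform methylome at a fixed per-site level, any-context mix
make_uniform_sample <- function(chrom_len = 10000L, spacing = 10L,
                                level = 0.5, cov = 10L,
                                contexts = c("CG", "CHG", "CHH")) {
  pos <- seq(5L, chrom_len - 5L, by = spacing)
  meth <- as.integer(round(level * cov))
  make_sample(pos, rep(meth, length(pos)), rep(cov - meth, length(pos)),
              context = rep_len(contexts, length(pos)),
              strand = rep_len(c("+", "-"), length(pos)),
              chrom_len = chrom_len)
}

# shared simulated demo dataset: built once per test run
.sim_cache <- new.env(parent = emptyenv())
get_demo_sim <- function(seed = 1L) {
  key <- paste0("demo_", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_dataset(default_landscape_plan(seed = seed))
  .sim_cache[[key]]
}
get_demo_pooled <- function(tissue, seed = 1L) {
  key <- paste0("pool_", tissue, "_", seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- get_demo_sim(seed)
    ids <- paste0(tissue, 1:3)
    .sim_cache[[key]] <- pool_samples(sim$samples[ids])
  }
  .sim_cache[[key]]
}

# ---- independent oracles ---------------------------------------------------

# enumerate-filter-merge DMV oracle: plain loops, no package internals
oracle_dmvs <- function(sample, params) {
  out <- list()
  for (ch in names(sample$chrom_sizes)) {
    len <- as.integer(sample$chrom_sizes[[ch]])
    s <- sample$sites
    keep <- s$chrom == ch & (s$meth + s$unmeth) >= params$min_site_cov
    pos <- s$pos[keep]
    lev <- s$meth[keep] / (s$meth[keep] + s$unmeth[keep])
    if (len < params$window_size) next
    starts <- seq.int(0L, len - params$window_size, by = params$step)
    ok <- logical(length(starts))
    for (i in seq_along(starts)) {
      inw <- pos > starts[i] & pos <= starts[i] + params$window_size
      ok[i] <- sum(inw) >= params$min_sites_per_window &&
        mean(lev[inw]) < params$max_level
    }
    qs <- starts[ok]
    if (!length(qs)) next
    cur_s <- qs[1L]; cur_e <- qs[1L] + params$window_size
    for (q in qs[-1L]) {
      if (q < cur_e) cur_e <- q + params$window_size
      else {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cur_s,
                                              end = cur_e)
        cur_s <- q; cur_e <- q + params$window_size
      }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cur_s,
                                          end = cur_e)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  do.call(rbind, out)
}

# random methylome instance for oracle equivalence checks
random_instance <- function(seed, max_len = 100000L) {
  set.seed(seed)
  len <- sample(2000:max_len, 1L)
  n <- max(10L, as.integer(len * runif(1, 0.02, 0.15)))
  pos <- sort(sample.int(len, n, replace = TRUE))
  cov <- rpois(n, 8)
  # blocky levels so valleys actually occur
  p <- ifelse(runif(n) < 0.4, 0.01, runif(n, 0, 1))
  meth <- rbinom(n, cov, p)
  make_sample(pos, meth, cov - meth,
              context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
              strand = sample(c("+", "-"), n, replace = TRUE),
              chrom_len = len)
}

# exact hypergeometric upper tail by summation over the support
oracle_hyper_upper <- function(N, K, n, k) {
  j <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# per-valley Jaccard between a planted interval and detected regions
valley_jaccard <- function(truth_row, detected) {
  ov <- detected[detected$chrom == truth_row$chrom &
                 detected$start < truth_row$end &
                 detected$end > truth_row$start, ]
  if (nrow(ov) == 0L) return(0)
  inter <- sum(pmin(ov$end, truth_row$end) - pmax(ov$start, truth_row$start))
  inter / (sum(ov$end - ov$start) + (truth_row$end - truth_row$start) - inter)
}

# null landscape: one background-only chromosome, identical tissues
null_plan <- function(seed, len = 500000L) {
  probs <- rbind(background = c(0.6, 0.45, 0.08))
  colnames(probs) <- c("CG", "CHG", "CHH")
  landscape_plan(c(chrN = as.integer(len)),
                 data.table(chrom = character(), start = integer(),
                            end = integer(), class = character()),
                 probs, seed = seed)
}
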