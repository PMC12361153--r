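#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` genes from a
#' universe of `N` that contains `K` "successes", the probability of seeing
#' at least the observed overlap `k`. The tail includes k itself — the
#' standard over-representation convention — and is computed in log space
#' by `phyper` for numerical stability.
#'
#' @param N universe size.
#' @param K size of the first set.
#' @param n size of the second set (the draw).
#' @param k observed overlap.
#' @return upper-tail probability in \[0, 1\].
#' @export
hypergeometric_upper_tail <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, n >= 0, k >= 0)
  if (K > N || n > N) stop("set larger than universe")
  if (k > min(K, n)) stop("overlap k exceeds min(K, n)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment of one gene set in another
#'
#' Over-representation of `set_a` within `set_b` against a gene universe,
#' by hypergeometric upper tail. The choice of universe matters: the
#' default in [run_pipeline()] is all genes with defined tau (expressed
#' somewhere), but any superset of both sets may be supplied.
#'
#' @param set_a,set_b character vectors of gene ids, subsets of `universe`.
#' @param universe character vector of gene ids.
#' @return list with `N`, `K`, `n`, `k`, `p_value` and `fold_enrichment`
#'   ((k/n)/(K/N)).
#' @export
set_enrichment <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    stop("gene(s) outside the universe: ",
         paste(head(c(out_a, out_b), 5L), collapse = ", "))
  N <- length(universe); K <- length(set_a); n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  list(N = N, K = K, n = n, k = k,
       p_value = hypergeometric_upper_tail(N, K, n, k),
       fold_enrichment = if (K > 0 && n > 0) (k / n) / (K / N) else NA_real_)
}
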