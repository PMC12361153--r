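#' Tau tissue-specificity index
#'
#' tau = sum_i (1 - x_i / max(x)) / (n - 1) over a gene's abundances across
#' n >= 2 tissues: 0 for uniform expression, 1 for single-tissue
#' expression; with two tissues it reduces to 1 - min/max. Computed on raw
#' (untransformed) abundances. Undefined (NA) for an all-zero gene.
#'
#' @param x numeric vector of non-negative abundances, length >= 2.
#' @return tau in \[0, 1\], or `NA` when all entries are zero.
#' @export
tau <- function(x) {
  stopifnot(length(x) >= 2L)
  if (any(x < 0)) stop("negative abundance")
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1L)
}

#' Per-gene tau table
#'
#' @param expr gene x tissue abundance matrix (see
#'   [read_expression_table()]).
#' @return data.table with `gene_id`, `tau` (`NA` for all-zero genes),
#'   `preferred_tissue` (argmax tissue; `NA` on ties), `max_value`.
#' @export
tau_table <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2L)
  mx <- apply(expr, 1L, max)
  tv <- apply(expr, 1L, tau)
  n_arg <- rowSums(expr == mx & mx > 0)
  pref <- colnames(expr)[max.col(expr, ties.method = "first")]
  pref[n_arg != 1L] <- NA_character_
  data.table(gene_id = rownames(expr), tau = tv, preferred_tissue = pref,
             max_value = mx)
}

#' Tissue-preferentially expressed genes
#'
#' Genes with defined tau >= `tau_min` and maximum abundance >=
#' `min_max_abundance`, assigned to their highest-expressing tissue. Genes
#' whose maximum is tied across tissues are excluded (and reported in the
#' `ties` attribute). The abundance floor keeps noise-only genes — zero
#' versus epsilon — from scoring tau = 1; set it to 0 to disable.
#'
#' @param expr gene x tissue abundance matrix.
#' @param tau_min specificity cutoff (default 0.99).
#' @param min_max_abundance abundance floor on the per-gene maximum
#'   (default 1).
#' @return named list, one sorted gene id vector per tissue.
#' @export
preferential_genes <- function(expr, tau_min = 0.99, min_max_abundance = 1) {
  tt <- tau_table(expr)
  keep <- !is.na(tt$tau) & tt$tau >= tau_min &
    tt$max_value >= min_max_abundance
  ties <- tt$gene_id[keep & is.na(tt$preferred_tissue)]
  tt <- tt[keep & !is.na(preferred_tissue)]
  out <- lapply(setNames(nm = colnames(expr)), function(ts)
    sort(tt$gene_id[tt$preferred_tissue == ts]))
  attr(out, "ties") <- ties
  out
}

#' Two-group fold-change classification
#'
#' A gene is "up in a" when (v_a + pseudocount) / (v_b + pseudocount) >=
#' `cutoff` (boundary inclusive), and symmetrically for b. The pseudocount
#' keeps zero denominators finite.
#'
#' @param expr gene x tissue abundance matrix.
#' @param tissue_a,tissue_b column names to compare.
#' @param cutoff fold-change cutoff (> 1; default 2).
#' @param pseudocount added to both values (default 0.01).
#' @return list with sorted gene id vectors `up_in_a` and `up_in_b`.
#' @export
fold_change_de <- function(expr, tissue_a, tissue_b, cutoff = 2,
                           pseudocount = 0.01) {
  stopifnot(cutoff > 1, all(c(tissue_a, tissue_b) %in% colnames(expr)))
  ratio <- (expr[, tissue_a] + pseudocount) / (expr[, tissue_b] + pseudocount)
  list(up_in_a = sort(rownames(expr)[ratio >= cutoff]),
       up_in_b = sort(rownames(expr)[ratio <= 1 / cutoff]))
}
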