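# Hypergeometric over-representation analysis against user-supplied gene
# sets.

#' Over-representation analysis (upper-tail hypergeometric)
#'
#' For each term set, with universe size `N`, term size `K` (after
#' restriction to the universe), query size `n` (query genes outside the
#' universe are dropped and counted) and overlap `k`, the p-value is the
#' exact upper tail `P(X >= k)` of the hypergeometric distribution. BH
#' adjustment is applied across terms.
#'
#' @param query_genes character vector of query gene ids.
#' @param term_sets named list of lists with `name` and `genes` (e.g. from
#'   [read_gmt()] or a `chemical_gene_sets`).
#' @param universe character vector of background gene ids.
#' @return data.frame with `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `fold_enrichment`, `p`, `adj_p`, sorted by `adj_p`; attribute
#'   `n_query_dropped` counts query genes outside the universe.
#' @export
ora <- function(query_genes, term_sets, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) .stopf("ora: empty universe")
  query <- intersect(unique(query_genes), universe)
  n_dropped <- length(unique(query_genes)) - length(query)
  n <- length(query)
  if (n == 0) .stopf("ora: empty query after restriction to universe")
  rows <- lapply(sort(names(term_sets)), function(id) {
    genes <- intersect(term_sets[[id]]$genes, universe)
    K <- length(genes)
    k <- length(intersect(query, genes))
    p <- if (k == 0) 1 else
      phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id,
               term_name = term_sets[[id]]$name %||% id,
               k = k, K = K, n = n, N = N,
               fold_enrichment = if (K > 0) (k / n) / (K / N) else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adj_p <- bh_adjust(res$p)
  res <- res[order(res$adj_p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_query_dropped") <- n_dropped
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
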