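#' Hypergeometric gene-set enrichment
#'
#' Over-representation of a query gene list in each set of a catalog:
#' with a universe of `N` genes, a set of size `K` and a query of size
#' `n` overlapping the set in `k` genes, the p value is
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`. Query genes outside
#' the universe are dropped with a warning; p values are BH-adjusted
#' across the catalog's sets.
#'
#' @param query character vector of gene symbols.
#' @param catalog a [gene_set_catalog()].
#' @return data.frame (set, k, n, K, N, p, p_adj) sorted by p.
#' @export
enrich_hypergeometric <- function(query, catalog) {
  query <- unique(query)
  universe <- catalog$universe
  outside <- setdiff(query, universe)
  if (length(outside) > 0)
    cpw_warn(length(outside), " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  if (length(query) == 0) stop("empty query after universe filtering")

  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(catalog$sets), function(nm) {
    members <- intersect(catalog$sets[[nm]], universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p), ]
}
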