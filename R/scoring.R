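#' Score a gene set with expression-matched control genes
#'
#' Per-spot gene-set score in the style used for anatomical annotation
#' of spatial transcriptomics: genes are binned by their mean
#' log-normalized expression across spots into `n_bins` equal-frequency
#' bins; for every set gene, `n_ctrl` control genes are drawn from its
#' bin (excluding set genes; with replacement when the bin is smaller
#' than `n_ctrl`), and the score of a spot is the mean expression of
#' the set genes minus the mean over the pooled control genes. Adding a
#' constant to the whole expression matrix leaves scores unchanged.
#'
#' @param expr genes x spots log-normalized matrix (rownames = genes),
#'   or a `normalized_expr` object.
#' @param set character vector of gene symbols; at least one must be
#'   present in the matrix.
#' @param n_bins number of expression bins.
#' @param n_ctrl number of control genes sampled per set gene.
#' @param seed seed for control-gene sampling.
#' @param set_name used in error messages.
#' @return named numeric vector of per-spot scores.
#' @export
score_gene_set <- function(expr, set, n_bins = 25L, n_ctrl = 50L,
                           seed = 1L, set_name = "gene set") {
  if (inherits(expr, "normalized_expr")) expr <- expr$expr
  genes <- rownames(expr)
  set <- intersect(set, genes)
  if (length(set) == 0)
    stop("no gene of '", set_name, "' is present in the expression matrix")

  gmeans <- rowMeans(expr)
  n_bins <- min(n_bins, length(genes))
  # equal-frequency bins on the rank of the mean (ties broken stably)
  bin <- ceiling(rank(gmeans, ties.method = "first") / length(gmeans) *
                   n_bins)
  names(bin) <- genes

  ctrl <- with_seed(seed, {
    unlist(lapply(set, function(g) {
      pool <- genes[bin == bin[g] & !(genes %in% set)]
      if (length(pool) == 0) {
        # degenerate bin: fall back to all non-set genes
        pool <- setdiff(genes, set)
      }
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }), use.names = FALSE)
  })

  set_mean <- colMeans(expr[set, , drop = FALSE])
  ctrl_mean <- colMeans(expr[ctrl, , drop = FALSE])
  set_mean - ctrl_mean
}

#' Score every set of a catalog
#'
#' @param expr as in [score_gene_set()].
#' @param catalog a [gene_set_catalog()].
#' @inheritParams score_gene_set
#' @return spots x sets matrix of scores.
#' @export
score_catalog <- function(expr, catalog, n_bins = 25L, n_ctrl = 50L,
                          seed = 1L) {
  sets <- names(catalog$sets)
  out <- vapply(seq_along(sets), function(i) {
    score_gene_set(expr, catalog$sets[[sets[i]]], n_bins, n_ctrl,
                   seed = child_seed(seed, i), set_name = sets[i])
  }, numeric(if (inherits(expr, "normalized_expr")) ncol(expr$expr)
             else ncol(expr)))
  colnames(out) <- sets
  out
}
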