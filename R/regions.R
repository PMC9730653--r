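#' Assign clusters to anatomical regions
#'
#' For every cluster, computes the mean gene-set score and the fraction
#' of score-positive spots for each candidate region, then applies a
#' dominance rule: with `S_max` the largest positive mean score of the
#' cluster, every region whose mean score is at least
#' `dominance_ratio * S_max` is assigned. A single qualifying region
#' yields that label; two or more yield a composite label joining the
#' constituent names (the deep-brain case, where pallidum,
#' hypothalamus, midbrain and pons score jointly); no positive region
#' yields `"unassigned"`. The positive fraction is reported as QC only
#' and does not enter the rule.
#'
#' @param clusters integer cluster ids per spot (0-based as returned by
#'   [cluster_spots()]).
#' @param region_scores spots x regions score matrix (e.g. from
#'   [score_catalog()]).
#' @param dominance_ratio tau in (0, 1].
#' @return object of class `region_assignment`: list with
#'   `cluster_region` (clusters x regions mean-score matrix),
#'   `positive_fraction` (same shape), `cluster_label` (named character
#'   vector) and `spot_region` (per-spot final label).
#' @export
assign_clusters_to_regions <- function(clusters, region_scores,
                                       dominance_ratio = 0.75) {
  stopifnot(dominance_ratio > 0, dominance_ratio <= 1,
            length(clusters) == nrow(region_scores))
  ids <- sort(unique(clusters))
  regions <- colnames(region_scores)
  if (is.null(regions)) stop("region_scores must have column names")

  mean_score <- t(vapply(ids, function(cl) {
    colMeans(region_scores[clusters == cl, , drop = FALSE])
  }, numeric(length(regions))))
  pos_frac <- t(vapply(ids, function(cl) {
    colMeans(region_scores[clusters == cl, , drop = FALSE] > 0)
  }, numeric(length(regions))))
  dimnames(mean_score) <- dimnames(pos_frac) <-
    list(as.character(ids), regions)

  cluster_label <- vapply(seq_along(ids), function(i) {
    s <- mean_score[i, ]
    if (all(s <= 0)) return("unassigned")
    keep <- regions[s >= dominance_ratio * max(s)]
    paste(keep, collapse = "+")
  }, character(1))
  names(cluster_label) <- as.character(ids)

  structure(
    list(cluster_region = mean_score, positive_fraction = pos_frac,
         cluster_label = cluster_label,
         spot_cluster = clusters,
         spot_region = unname(cluster_label[as.character(clusters)])),
    class = "region_assignment"
  )
}

#' @export
print.region_assignment <- function(x, ...) {
  cat("region_assignment:\n")
  for (cl in names(x$cluster_label)) {
    cat(sprintf("  cluster %s -> %s (n = %d)\n", cl, x$cluster_label[cl],
                sum(x$spot_cluster == as.integer(cl))))
  }
  invisible(x)
}

#' Annotate a spatial dataset end to end
#'
#' Convenience wrapper: normalize, score the catalog's anatomical sets,
#' cluster with a target count and assign regions. The deep-brain
#' composite label is collapsed to `"DEEP"` in `spot_region_coarse` for
#' comparison with planted truth.
#'
#' @param dataset a [spatial_dataset()].
#' @param catalog a [gene_set_catalog()] whose anatomical sets are
#'   named by region.
#' @param target_clusters Leiden cluster-count constraint.
#' @param n_pcs,k_neighbors,n_bins,n_ctrl,dominance_ratio,seed see the
#'   stage functions.
#' @return list with `normalized`, `scores`, `clusters`, `assignment`
#'   and `spot_region_coarse`.
#' @export
annotate_spatial <- function(dataset, catalog = default_marker_sets(),
                             target_clusters = 5L, n_pcs = 30L,
                             k_neighbors = 15L, n_bins = 25L,
                             n_ctrl = 50L, dominance_ratio = 0.75,
                             seed = 1L) {
  norm <- normalize_counts(dataset)
  anat <- intersect(anatomical_regions(), names(catalog$sets))
  scores <- score_catalog(norm, gene_set_catalog(
    catalog$sets[anat], catalog$universe, catalog$provenance),
    n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  clusters <- cluster_spots(norm, n_pcs = n_pcs,
                            k_neighbors = k_neighbors,
                            target_clusters = target_clusters,
                            seed = seed)
  assignment <- assign_clusters_to_regions(clusters, scores,
                                           dominance_ratio)
  coarse <- assignment$spot_region
  deep <- paste(sort(deep_constituents()), collapse = "+")
  is_deep <- vapply(strsplit(coarse, "+", fixed = TRUE), function(p) {
    length(p) >= 2 && all(p %in% deep_constituents())
  }, logical(1))
  coarse[is_deep] <- "DEEP"
  list(normalized = norm, scores = scores, clusters = clusters,
       assignment = assignment, spot_region_coarse = coarse)
}
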