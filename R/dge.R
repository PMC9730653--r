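#' Two-sided Wilcoxon rank-sum test
#'
#' Core test used for region-stratified differential expression and the
#' knockout group comparisons. For two groups of sizes at most
#' `exact_max` each, the p value is computed by exhaustive enumeration
#' of all group assignments of the pooled (tied) ranks; the permutation
#' distribution of the Mann-Whitney U statistic is symmetric about
#' `n1*n2/2` (negating the pooled values reverses ranks and maps U to
#' `n1*n2 - U`), so the two-sided p is `P(|U - n1*n2/2| >= |u -
#' n1*n2/2|)`. Larger groups use the normal approximation with the tie
#' correction and no continuity correction. Degenerate pools (zero tie-
#' corrected variance) return p = 1.
#'
#' @param x,y numeric vectors.
#' @param exact_max use exact enumeration when both groups are at most
#'   this size.
#' @return list with `statistic` (U), `p_value`, `method`.
#' @export
ranksum_test <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  center <- n1 * n2 / 2

  if (n1 <= exact_max && n2 <= exact_max) {
    sums <- combn_rank_sums(r, n1)
    us <- sums - n1 * (n1 + 1) / 2
    p <- mean(abs(us - center) >= abs(u - center) - 1e-9)
    return(list(statistic = u, p_value = p, method = "exact"))
  }

  nt <- n1 + n2
  ties <- table(r)
  v <- (n1 * n2 / 12) *
    ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
  if (v <= 0) return(list(statistic = u, p_value = 1,
                          method = "degenerate"))
  z <- (u - center) / sqrt(v)
  list(statistic = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

# rank sums of group 1 over all assignments of n1 pooled ranks
combn_rank_sums <- function(r, n1) {
  utils::combn(length(r), n1, function(idx) sum(r[idx]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control via [stats::p.adjust()]. Values
#' that are `NA`/`NaN` propagate unchanged and are excluded from the
#' ranking (the effective test count is the number of finite p values).
#'
#' @param p numeric vector of p values in `[0, 1]` (NA allowed).
#' @return adjusted p values, same order as input.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0, 1]")
  out <- p
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Region-stratified differential expression vs. control
#'
#' Per-gene two-sided Wilcoxon rank-sum test comparing the spots of one
#' region at one post-injection time point against the same region in
#' the uninjected control, on log-normalized expression. The fold
#' change is `log2((mean(expm1(x)) + eps) / (mean(expm1(ctrl)) + eps))`.
#' Regions with fewer than `min_spots` spots in either group are
#' skipped with a warning (`NULL` return).
#'
#' @param norm a `normalized_expr` (or genes x spots matrix).
#' @param regions per-spot region labels.
#' @param times per-spot time in hours (0 = control).
#' @param region region to test.
#' @param time_h post-injection time point to test.
#' @param control_time time value identifying the control group.
#' @param min_spots minimum group size.
#' @param eps fold-change pseudocount.
#' @return data.frame (gene, region, time_h, stat, p, p_adj, log2fc,
#'   n_group, n_control) or `NULL` if skipped.
#' @export
rank_genes_wilcoxon <- function(norm, regions, times, region, time_h,
                                control_time = 0, min_spots = 3L,
                                eps = 1e-9) {
  expr <- if (inherits(norm, "normalized_expr")) norm$expr else norm
  g1 <- which(regions == region & times == time_h)
  g0 <- which(regions == region & times == control_time)
  if (length(g1) < min_spots || length(g0) < min_spots) {
    cpw_warn("region '", region, "' at ", time_h,
             " h has a group below ", min_spots, " spots; skipped")
    return(NULL)
  }
  res <- apply(expr, 1, function(v) {
    t <- ranksum_test(v[g1], v[g0])
    c(t$statistic, t$p_value)
  })
  mu1 <- rowMeans(expm1(expr[, g1, drop = FALSE]))
  mu0 <- rowMeans(expm1(expr[, g0, drop = FALSE]))
  data.frame(
    gene = rownames(expr), region = region, time_h = time_h,
    stat = res[1, ], p = res[2, ], p_adj = bh_adjust(res[2, ]),
    log2fc = log2((mu1 + eps) / (mu0 + eps)),
    n_group = length(g1), n_control = length(g0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Run the differential expression over all regions and time points
#'
#' @inheritParams rank_genes_wilcoxon
#' @param time_points time points to test (default: all nonzero times
#'   present).
#' @param region_set regions to test (default: all labels present).
#' @return one combined data.frame of [rank_genes_wilcoxon()] results.
#' @export
dge_all_regions <- function(norm, regions, times,
                            time_points = NULL, region_set = NULL,
                            control_time = 0, min_spots = 3L) {
  time_points <- time_points %||% sort(unique(times[times != control_time]))
  region_set <- region_set %||% sort(unique(regions))
  out <- list()
  for (rg in region_set) for (tp in time_points) {
    res <- rank_genes_wilcoxon(norm, regions, times, rg, tp,
                               control_time, min_spots)
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  do.call(rbind, out)
}

#' Top-k up-regulated marker table
#'
#' Per time point (within one region's results), the `k` genes with the
#' smallest adjusted p among up-regulated genes (`log2fc > 0`); ties
#' are broken by decreasing `|log2fc|`, then gene symbol. Time points
#' with fewer than `k` up-regulated genes contribute what exists and
#' are flagged in the `short` attribute.
#'
#' @param dge data.frame from [dge_all_regions()] (one or more regions).
#' @param k table depth per time point.
#' @return data.frame (region, time_h, rank, gene, p_adj, log2fc); the
#'   union of genes across time points is the heatmap row set.
#' @export
top_k_table <- function(dge, k = 5L) {
  stopifnot(k >= 1)
  short <- character(0)
  pieces <- list()
  for (rg in unique(dge$region)) for (tp in sort(unique(dge$time_h))) {
    d <- dge[dge$region == rg & dge$time_h == tp & dge$log2fc > 0, ]
    if (nrow(d) == 0) next
    ord <- order(d$p_adj, -abs(d$log2fc), d$gene)
    d <- d[ord, ][seq_len(min(k, nrow(d))), ]
    if (nrow(d) < k)
      short <- c(short, sprintf("%s@%gh", rg, tp))
    pieces[[length(pieces) + 1L]] <- data.frame(
      region = rg, time_h = tp, rank = seq_len(nrow(d)),
      gene = d$gene, p_adj = d$p_adj, log2fc = d$log2fc,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  attr(out, "short") <- short
  out
}
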