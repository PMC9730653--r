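#' Cluster spots with a target cluster count
#'
#' PCA on the log-normalized expression, a k-nearest-neighbor graph on
#' the principal-component coordinates, and Leiden community detection
#' (modularity objective). The Leiden resolution is searched by
#' bisection on `[r_lo, r_hi]` until the number of communities equals
#' `target_clusters`; on plateaus the smallest such resolution is kept.
#' The community count is checked to be non-decreasing along the search
#' trace; a violated bracket is re-bisected from scratch once with a
#' fresh seed stream.
#'
#' @param expr genes x spots matrix or `normalized_expr`.
#' @param n_pcs number of principal components.
#' @param k_neighbors neighbors for the kNN graph.
#' @param target_clusters required number of communities.
#' @param seed seed for PCA-free stochastic steps (Leiden refinement).
#' @param r_lo,r_hi resolution search bracket.
#' @param max_iter maximum bisection steps.
#' @return integer vector of cluster ids `0..target_clusters-1`,
#'   ordered by decreasing cluster size, with the search trace in the
#'   `trace` attribute (data.frame: resolution, n_communities).
#' @export
cluster_spots <- function(expr, n_pcs = 30L, k_neighbors = 15L,
                          target_clusters = 5L, seed = 1L,
                          r_lo = 0.05, r_hi = 2.0, max_iter = 60L) {
  if (inherits(expr, "normalized_expr")) expr <- expr$expr
  n <- ncol(expr)
  if (n < target_clusters)
    stop("fewer spots (", n, ") than target clusters")
  if (target_clusters == 1L) {
    out <- rep(0L, n)
    attr(out, "trace") <- data.frame(resolution = numeric(0),
                                     n_communities = integer(0))
    return(out)
  }

  pcs <- spot_pcs(expr, n_pcs)
  g <- knn_graph(pcs, k_neighbors)

  leiden_at <- function(r, s) {
    with_seed(s, igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = r,
      n_iterations = 3))$membership
  }
  n_comm <- function(memb) length(unique(memb))

  search <- function(stream) {
    lo <- r_lo; hi <- r_hi
    m_lo <- leiden_at(lo, child_seed(seed, stream))
    m_hi <- leiden_at(hi, child_seed(seed, stream + 1L))
    trace <- data.frame(resolution = c(lo, hi),
                        n_communities = c(n_comm(m_lo), n_comm(m_hi)))
    if (n_comm(m_lo) == target_clusters)
      return(list(memb = m_lo, trace = trace, ok = TRUE))
    if (n_comm(m_hi) == target_clusters)
      best <- list(r = hi, memb = m_hi)
    else best <- NULL
    if (n_comm(m_lo) > target_clusters || n_comm(m_hi) < target_clusters)
      return(list(trace = trace, ok = FALSE))
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      m <- leiden_at(mid, child_seed(seed, stream + 1L + it))
      k <- n_comm(m)
      trace <- rbind(trace, data.frame(resolution = mid,
                                       n_communities = k))
      if (k >= target_clusters) {
        if (k == target_clusters) best <- list(r = mid, memb = m)
        hi <- mid
      } else {
        lo <- mid
      }
      if (!is.null(best) && hi - lo < 1e-4) break
    }
    list(memb = best$memb, trace = trace, ok = !is.null(best))
  }

  res <- search(1L)
  # monotonicity audit on the trace: count should be non-decreasing in
  # resolution; restart once on a violation
  if (res$ok && trace_violates(res$trace)) res <- search(1000L)
  if (!res$ok || is.null(res$memb)) {
    tr <- res$trace
    ach <- sort(unique(tr$n_communities))
    stop("resolution search could not reach ", target_clusters,
         " clusters; achievable counts bracket: ",
         paste(range(ach), collapse = "-"))
  }

  memb <- res$memb
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  out <- unname(relabel[as.character(memb)])
  attr(out, "trace") <- res$trace
  out
}

trace_violates <- function(trace) {
  tr <- trace[order(trace$resolution), ]
  any(diff(tr$n_communities) < 0)
}

spot_pcs <- function(expr, n_pcs) {
  n_pcs <- min(n_pcs, nrow(expr) - 1L, ncol(expr) - 1L)
  pr <- prcomp(t(expr), center = TRUE, scale. = FALSE, rank. = n_pcs)
  pr$x
}

# exact kNN by blocked euclidean distances; undirected union graph
knn_graph <- function(x, k, block = 2048L) {
  n <- nrow(x)
  k <- min(k, n - 1L)
  sq <- rowSums(x^2)
  nn <- matrix(0L, n, k)
  for (start in seq(1, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(x[idx, , drop = FALSE], x)
    d2[cbind(seq_along(idx), idx)] <- Inf
    nn[idx, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}
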