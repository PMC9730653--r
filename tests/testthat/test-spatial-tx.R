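toy_dataset <- function(counts) {
  n <- ncol(counts)
  spatial_dataset(
    counts, genes = paste0("g", seq_len(nrow(counts))),
    positions = data.frame(
      barcode = paste0("b", seq_len(n)), sample_id = "s1",
      in_tissue = 1L, array_row = seq_len(n), array_col = 1L,
      pxl_row_in_fullres = seq_len(n), pxl_col_in_fullres = 1L),
    meta = data.frame(barcode = paste0("b", seq_len(n)),
                      sample_id = "s1", animal = "a", time_h = 0,
                      genotype = "wildtype"))
}

test_that("normalization scales each spot to the median total", {
  # two spots with totals 100 and 300: median 200, factors x2 and x2/3
  counts <- matrix(c(40, 60, 120, 180), 2, 2)
  norm <- normalize_counts(toy_dataset(counts))
  expect_equal(norm$expr[1, 1], log1p(40 * 2))
  expect_equal(norm$expr[2, 2], log1p(180 * 2 / 3))
  expect_true(all(norm$expr >= 0))

  # equal totals: scaling is the identity before log
  eq <- matrix(c(30, 70, 60, 40), 2, 2)
  norm_eq <- normalize_counts(toy_dataset(eq))
  expect_equal(norm_eq$expr, log1p(eq), ignore_attr = TRUE)
})

test_that("zero-count spots are dropped with a warning", {
  counts <- matrix(c(5, 5, 0, 0, 3, 7), 2, 3)
  expect_message(norm <- normalize_counts(toy_dataset(counts)), "dropped")
  expect_equal(ncol(norm$expr), 2L)
})

test_that("gene-set scores are zero on constant input and match a hand computation", {
  const <- matrix(3, 6, 4, dimnames = list(paste0("g", 1:6), NULL))
  expect_equal(unname(score_gene_set(const, c("g1", "g2"), seed = 1)),
               rep(0, 4))

  # one bin: controls are drawn from the 4 non-set genes, so the score
  # is mean(set) - mean(non-set control draws); with n_ctrl large the
  # pooled control mean is the mean over sampled non-set genes
  set.seed(42)
  expr <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("g", 1:6),
                                                  NULL))
  sc <- score_gene_set(expr, c("g1", "g2"), n_bins = 1, n_ctrl = 2000,
                       seed = 7)
  hand <- colMeans(expr[c("g1", "g2"), ]) - colMeans(expr[3:6, ])
  expect_lt(max(abs(sc - hand)), 0.05)
})

test_that("scores are invariant to a constant expression shift", {
  set.seed(1)
  expr <- matrix(rexp(300), 30, 10,
                 dimnames = list(paste0("g", 1:30), NULL))
  for (shift in c(-1, 2.5)) {
    a <- score_gene_set(expr, c("g3", "g7", "g11"), n_bins = 5,
                        seed = 3)
    b <- score_gene_set(expr + shift, c("g3", "g7", "g11"), n_bins = 5,
                        seed = 3)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("spots in the planted choroid plexus score highest for the CP set", {
  ann <- test_annotation()
  truth <- test_spot_cohort()$truth$region
  by_region <- tapply(ann$scores[, "CP"], truth, mean)
  expect_equal(names(which.max(by_region)), "CP")
})

test_that("clustering honors the target cluster count", {
  set.seed(2)
  # two well-separated expression blobs
  expr <- cbind(matrix(rnorm(50 * 40, 0), 50),
                matrix(rnorm(50 * 40, 6), 50))
  rownames(expr) <- paste0("g", 1:50)
  cl <- cluster_spots(expr, n_pcs = 10, k_neighbors = 10,
                      target_clusters = 2, seed = 1)
  expect_equal(length(unique(cl)), 2L)
  expect_true(all(tapply(rep(1:2, each = 40), cl, function(x)
    length(unique(x))) == 1))

  one <- cluster_spots(expr, target_clusters = 1, seed = 1)
  expect_equal(unique(one), 0L)
})

test_that("the resolution search trace is monotone and hits five clusters", {
  ann <- test_annotation()
  cl <- ann$clusters
  expect_equal(sort(unique(cl)), 0:4)
  tr <- attr(cl, "trace")
  tr <- tr[order(tr$resolution), ]
  expect_true(all(diff(tr$n_communities) >= 0))
  # labels ordered by decreasing size
  sizes <- as.numeric(table(cl)[as.character(0:4)])
  expect_true(all(diff(sizes) <= 0))
})

test_that("the dominance rule assigns single, composite and unassigned labels", {
  scores <- rbind(
    c(CP = 0.9, CTX = 0.1, PAL = 0.05, HY = 0.02, MB = 0.01, P = 0.0),
    c(CP = 0.05, CTX = 0.02, PAL = 0.50, HY = 0.48, MB = 0.45,
      P = 0.44),
    c(CP = -0.2, CTX = -0.1, PAL = -0.3, HY = -0.5, MB = -0.2,
      P = -0.4))
  spots <- rep(0:2, each = 4)
  mat <- scores[spots + 1, ]
  asg <- assign_clusters_to_regions(spots, mat, dominance_ratio = 0.75)
  expect_equal(unname(asg$cluster_label["0"]), "CP")
  expect_equal(unname(asg$cluster_label["1"]), "PAL+HY+MB+P")
  expect_equal(unname(asg$cluster_label["2"]), "unassigned")
  expect_equal(dim(asg$cluster_region), c(3L, 6L))
  expect_true(all(nzchar(asg$spot_region)))
})

test_that("region labels recover the planted anatomy (ARI >= 0.8)", {
  ann <- test_annotation()
  truth <- test_spot_cohort()$truth$region
  ari <- mclust::adjustedRandIndex(ann$spot_region_coarse, truth)
  expect_gte(ari, 0.8)
})
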