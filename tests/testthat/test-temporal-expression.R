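test_that("the rank-sum test matches exhaustive enumeration for small groups", {
  set.seed(10)
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- sample(1:5, n1, replace = TRUE)  # ties on purpose
    y <- sample(2:7, n2, replace = TRUE)
    expect_equal(ranksum_test(x, y)$p_value, oracle_ranksum_p(x, y),
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
  # tie-free case against the reference implementation
  x <- c(1.3, 2.7, 0.2, 5.1); y <- c(3.3, 4.4, 6.2, 0.9, 2.2)
  expect_equal(ranksum_test(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value)
  expect_equal(ranksum_test(1:3, 4:6)$p_value, 0.1)
})

test_that("identical groups give p = 1 and log2FC = 0", {
  expr <- matrix(rep(c(1, 2, 3, 1, 2, 3), each = 4), nrow = 4)
  rownames(expr) <- paste0("g", 1:4)
  res <- rank_genes_wilcoxon(expr, regions = rep("CP", 6),
                             times = rep(c(12, 0), each = 3),
                             region = "CP", time_h = 12)
  expect_equal(res$p, rep(1, 4))
  expect_equal(res$log2fc, rep(0, 4))
  expect_true(all(res$p_adj >= res$p - 1e-12))
})

test_that("groups below the minimum size are skipped with a warning", {
  expr <- matrix(1:12, 2, dimnames = list(c("a", "b"), NULL))
  expect_message(
    res <- rank_genes_wilcoxon(expr, rep(c("CP", "STR"), 3),
                               rep(c(0, 12), each = 3), "CP", 12),
    "skipped")
  expect_null(res)
})

test_that("BH adjustment matches the hand step-up and its invariances", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))

  set.seed(3)
  p <- runif(40)
  expect_equal(bh_adjust(p), oracle_bh(p))
  perm <- sample(40)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_true(all(bh_adjust(p) >= p))

  withnan <- c(0.01, NaN, 0.5)
  adj <- bh_adjust(withnan)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], oracle_bh(c(0.01, 0.5)))
})

test_that("type-I error is nominal on null negative-binomial genes", {
  set.seed(99)
  n <- 40
  counts <- matrix(rnbinom(3000 * 2 * n, mu = 20, size = 5), nrow = 3000)
  grp <- rep(c(0, 12), each = n)
  p <- apply(counts, 1, function(v) {
    ranksum_test(v[grp == 0], v[grp == 12])$p_value
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("top-k tables obey size, ties and flagging rules", {
  mk <- function(gene, time_h, p_adj, lfc) {
    data.frame(gene = gene, region = "CP", time_h = time_h, stat = 0,
               p = p_adj, p_adj = p_adj, log2fc = lfc,
               n_group = 5, n_control = 5)
  }
  # 6 time points x 6 distinct up genes: exactly 30 rows
  dge <- do.call(rbind, lapply(c(2, 12, 24, 36, 48, 96), function(tp) {
    mk(sprintf("t%d_g%d", tp, 1:6), tp, seq(0.001, 0.006, by = 0.001),
       1)
  }))
  tab <- top_k_table(dge, 5)
  expect_equal(nrow(tab), 30L)

  # tie at rank k: equal p and |lfc| -> alphabetical gene wins
  tie <- mk(c("zeta", "alpha", "mid"), 2, c(0.01, 0.01, 0.001),
            c(2, 2, 1))
  expect_equal(top_k_table(tie, 2)$gene, c("mid", "alpha"))

  # down-regulated genes never enter; short columns are flagged
  updown <- mk(c("up1", "down1"), 2, c(0.01, 0.001), c(1, -2))
  t2 <- top_k_table(updown, 5)
  expect_equal(t2$gene, "up1")
  expect_equal(attr(t2, "short"), "CP@2h")
})

test_that("planted wave genes top their region/time marker tables", {
  dge <- test_dge()
  top_cp <- top_k_table(dge[dge$region == "CP", ], 5)
  cp_wave <- c("Icam1", "Ccl20", "Cxcl10", "Ccl5", "Irf7", "Ifi27l2a",
               "Vcam1", "Bst2", "Serpina3n", "Lcn2")
  expect_true(all(top_cp$gene[top_cp$time_h == 12] %in% cp_wave))

  top_str <- top_k_table(dge[dge$region == "STR", ], 5)
  str_late <- c("Cd68", "Lyz2", "Hmox1", "Ftl1", "Mpeg1", "C1qa")
  expect_true(all(top_str$gene[top_str$time_h == 96] %in% str_late))
  expect_false(any(top_str$gene[top_str$time_h != 96] %in% str_late))
})

test_that("hypergeometric enrichment matches brute force and Fisher", {
  uni <- sprintf("g%02d", 1:20)
  catalog <- gene_set_catalog(list(s = uni[1:5], all = uni), uni)
  res <- enrich_hypergeometric(uni[c(1:4, 10)], catalog)
  expect_equal(res$p[res$set == "s"], oracle_hyper_p(20, 5, 5, 4))
  expect_equal(res$p[res$set == "s"], 76 / 15504, tolerance = 1e-12)
  expect_equal(res$p[res$set == "all"], 1)

  set.seed(5)
  for (i in 1:20) {
    N <- sample(15:60, 1); K <- sample(3:10, 1); n <- sample(3:12, 1)
    k <- sample(0:min(n, K), 1)
    p_oracle <- oracle_hyper_p(N, K, n, k)
    p_fisher <- fisher.test(
      matrix(c(k, K - k, n - k, N - K - (n - k)), 2),
      alternative = "greater")$p.value
    expect_equal(p_oracle, p_fisher, tolerance = 1e-10)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 p_oracle, tolerance = 1e-12)
  }
})

test_that("enrichment rejects empty queries and drops outsiders", {
  catalog <- gene_set_catalog(list(s = c("a", "b")), c("a", "b", "c"))
  expect_error(enrich_hypergeometric("zzz", catalog), "empty query")
  expect_message(res <- enrich_hypergeometric(c("a", "zzz"), catalog),
                 "dropped")
  expect_equal(res$n, 1)
})

test_that("the pathway score time course recovers the planted CP peak", {
  ann <- test_annotation()
  ds <- test_spot_cohort()
  tc <- gene_set_time_course(
    ann$normalized, default_marker_sets()$sets$MYD88_TLR_SIGNALING,
    ds$truth$region, ds$meta$time_h, "CP", B = 2000, seed = 1)
  expect_true(tc$peak$peak_time_h %in% c(12, 24))
  expect_true(all(tc$summary$reliable))

  # delegation: summaries are computed from score_gene_set outputs
  sc <- score_gene_set(ann$normalized,
                       default_marker_sets()$sets$MYD88_TLR_SIGNALING,
                       seed = 1)
  sel <- ds$truth$region == "CP" & ds$meta$time_h == 24
  expect_equal(tc$summary$median[tc$summary$time_h == 24],
               median(sc[sel]))
})

test_that("a null cohort yields a flat score time course", {
  lay <- test_layout()
  ds <- generate_spot_cohort(
    lay, cohort_design(c(0, 2, 12, 24, 48, 96), 1L, "wildtype",
                       seed = 21), programs = list())
  norm <- normalize_counts(ds)
  tc <- gene_set_time_course(
    norm, default_marker_sets()$sets$MYD88_TLR_SIGNALING,
    ds$truth$region, ds$meta$time_h, "CP", B = 2000, seed = 2)
  overall <- median(tc$scores$score)
  expect_true(all(tc$summary$lo <= overall & overall <= tc$summary$hi))
})
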