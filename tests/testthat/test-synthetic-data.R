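test_that("layout masks are disjoint, contained and non-empty", {
  lay <- test_layout()
  stack <- Reduce(`+`, lapply(lay$region_masks, function(m) m * 1L))
  expect_true(all(stack <= 1L))
  expect_true(all(!(stack == 1L & !lay$outline)))
  expect_true(all(vapply(lay$region_masks, sum, numeric(1)) > 0))
})

test_that("invalid layouts are rejected", {
  lay <- test_layout()
  bad <- lay$region_masks
  bad$CTX[which(bad$TH)[1]] <- TRUE  # overlap with TH
  expect_error(
    section_layout(lay$width_px, lay$height_px, lay$px_size_um, bad,
                   lay$outline),
    "overlap")
  empty <- lay$region_masks
  empty$TH[] <- FALSE
  expect_error(
    section_layout(lay$width_px, lay$height_px, lay$px_size_um, empty,
                   lay$outline),
    "empty")
})

test_that("spot cohorts are deterministic given the seed", {
  lay <- test_layout()
  d <- cohort_design(c(0, 96), 1L, "wildtype", seed = 7)
  a <- generate_spot_cohort(lay, d)
  b <- generate_spot_cohort(lay, d)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$truth, b$truth)
  c <- generate_spot_cohort(lay, cohort_design(c(0, 96), 1L,
                                               "wildtype", seed = 8))
  expect_false(identical(as.matrix(a$counts), as.matrix(c$counts)))
})

test_that("without programs, expression is time-invariant", {
  lay <- test_layout()
  ds <- generate_spot_cohort(lay, cohort_design(c(0, 48), 1L,
                                                "wildtype", seed = 5),
                             programs = list())
  tm <- ds$meta$time_h
  counts <- as.matrix(ds$counts)
  p <- apply(counts, 1, function(v) {
    ranksum_test(v[tm == 0], v[tm == 48])$p_value
  })
  expect_gte(mean(p >= 0.01), 0.99)
})

test_that("a single planted program yields the analytic mean ratio", {
  lay <- test_layout()
  base <- default_baseline()
  prog <- list(temporal_program("one", "Gene0001", "STR", 96, 4,
                                width = 0.35))
  ds <- generate_spot_cohort(lay, cohort_design(c(0, 96), 1L,
                                                "wildtype", seed = 9),
                             programs = prog, baseline = base)
  str_idx <- ds$truth$region == "STR"
  g <- which(ds$genes == "Gene0001")
  m96 <- mean(ds$counts[g, str_idx & ds$meta$time_h == 96])
  m0 <- mean(ds$counts[g, str_idx & ds$meta$time_h == 0])
  # analytic ratio: fold 4 deflated by the compositional normalizer
  # (relative expression is renormalized to sum 1 per spot)
  mf <- attr(base, "marker_fold")
  sum_base <- function(fold_g1) {
    s <- base$base_expr
    s[!is.na(base$marker_region) & base$marker_region == "STR"] <-
      s[!is.na(base$marker_region) & base$marker_region == "STR"] * mf
    tot <- sum(s)
    tot + s[base$gene == "Gene0001"] * (fold_g1 - 1)
  }
  expected <- 4 * sum_base(1) / sum_base(4)
  expect_lt(abs(m96 / m0 - expected) / expected, 0.15)
})

test_that("erythrocyte transcripts peak at 2 h in CP and striatum", {
  ds <- test_spot_cohort()
  norm <- normalize_counts(ds)
  ery <- c("Hba-a1", "Hba-a2", "Hbb-bs", "Hbb-bt", "Alas2")
  for (rg in c("CP", "STR")) {
    sel <- ds$truth$region == rg
    sc <- score_gene_set(norm$expr[, sel], ery, seed = 1)
    by_t <- tapply(sc, ds$meta$time_h[sel], mean)
    expect_equal(as.numeric(names(which.max(by_t))), 2)
  }
})

test_that("planted pose jitter displaces the mask centroid exactly", {
  lay <- test_layout()
  tr <- similarity_transform(10, 1, c(5, -3))
  sec <- render_section(lay, tr, "Hoechst", 24, "wildtype", seed = 4)
  tmpl <- layout_label_image(lay)
  ctr_t <- colMeans(which(tmpl$labels > 0, arr.ind = TRUE))
  expected <- as.numeric(apply_transform(tr, matrix(ctr_t, 1)))
  observed <- colMeans(which(sec$mask > 0, arr.ind = TRUE))
  expect_lt(max(abs(observed - expected)), 0.5)
})

test_that("sham sections carry no ICAM1 signal above background", {
  lay <- test_layout()
  sec <- render_section(lay, similarity_transform(), "ICAM1", 36,
                        "sham", seed = 6)
  cp <- compartment_mean_intensity(sec, "ICAM1",
                                   c("CP_ipsi", "STR_contra"),
                                   normalize = FALSE)
  expect_lt(abs(cp[["CP_ipsi"]] - cp[["STR_contra"]]), 15)
})

test_that("wildtype dextran leakage area is maximal at 48 h among late times", {
  lay <- test_layout()
  secs <- lapply(c(24, 48, 96), function(tp) {
    render_section(lay, similarity_transform(), "dextran70", tp,
                   "wildtype", seed = 20 + tp)
  })
  areas <- leakage_table(secs)$area_mm2
  expect_equal(which.max(areas), 2L)
})

test_that("unknown channels are rejected", {
  lay <- test_layout()
  expect_error(render_section(lay, similarity_transform(), "GFAP", 2,
                              "wildtype"),
               "unknown channel")
  expect_error(generate_section_cohort(lay, cohort_design(2, 1L),
                                       channels = "nope"),
               "unknown channel")
})

test_that("fixture bundles round-trip bit-exactly", {
  ds <- test_tiny_cohort()
  dir <- withr::local_tempdir()
  write_fixture_bundle(ds, dir, catalog = default_marker_sets(),
                       force = TRUE)
  hdr <- readLines(file.path(dir, "matrix.mtx"), n = 2)
  expect_match(hdr[1], "coordinate integer")
  expect_equal(as.integer(strsplit(hdr[2], " ")[[1]][1:2]), dim(ds))

  back <- read_spatial_bundle(dir)
  expect_identical(as.matrix(back$counts), as.matrix(ds$counts))
  expect_equal(back$genes, ds$genes)
  expect_equal(back$meta$time_h, ds$meta$time_h)
  expect_equal(back$truth$region, ds$truth$region)

  expect_error(write_fixture_bundle(ds, dir), "force")
})

test_that("GMT lines reparse with member order preserved", {
  catalog <- gene_set_catalog(
    list(CP_markers = c("Ttr", "Folr1", "Clic6"),
         other = c("Gm1", "Gm2")),
    universe = c("Ttr", "Folr1", "Clic6", "Gm1", "Gm2"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(catalog, path)
  back <- read_gmt(path)
  expect_identical(back$sets$CP_markers, c("Ttr", "Folr1", "Clic6"))
  expect_identical(names(back$sets), names(catalog$sets))
})
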