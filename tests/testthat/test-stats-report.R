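test_that("bootstrap intervals: degenerate, exhaustive and deterministic", {
  expect_equal(as.numeric(bootstrap_ci(rep(3.5, 6), B = 500, seed = 1)),
               c(3.5, 3.5))
  expect_message(ci1 <- bootstrap_ci(2, B = 100, seed = 1),
                 "degenerate")
  expect_equal(as.numeric(ci1), c(2, 2))

  # n = 3: the exact percentile interval from all 27 resample means
  oracle <- oracle_boot_exhaustive(c(1, 2, 3), 0.95)
  mc <- bootstrap_ci(c(1, 2, 3), 0.95, B = 20000L, seed = 42)
  expect_equal(as.numeric(mc), as.numeric(oracle), tolerance = 0.05)

  a <- bootstrap_ci(rnorm(20), B = 2000, seed = 7)
  b <- bootstrap_ci_same <- bootstrap_ci(rnorm(20), B = 2000, seed = 7)
  set.seed(1); x <- rnorm(20)
  expect_identical(bootstrap_ci(x, B = 2000, seed = 7),
                   bootstrap_ci(x, B = 2000, seed = 7))
})

test_that("bootstrap endpoints lie inside the convex hull of the data", {
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    ci <- bootstrap_ci(x, B = 1000, seed = i)
    expect_gte(ci[["lo"]], min(x))
    expect_lte(ci[["hi"]], max(x))
    expect_lte(ci[["lo"]], mean(x))
    expect_gte(ci[["hi"]], mean(x))
  }
})

test_that("loess reproduces lines exactly and quadratics closely", {
  t <- seq(2, 96, length.out = 12)
  y <- 3 + 0.5 * t
  fit <- loess_fit(t, y, span = 0.75)
  expect_lt(max(abs(fit$fit - (3 + 0.5 * fit$time))), 1e-8)

  cfit <- loess_fit(t, rep(5, 12), span = 0.75)
  expect_lt(max(abs(cfit$fit - 5)), 1e-8)
  expect_lt(max(cfit$se), 1e-6)

  yq <- t^2
  qfit <- loess_fit(t, yq, span = 0.5)
  expect_lt(max(abs(qfit$fit - qfit$time^2)), 0.05 * diff(range(yq)))

  expect_error(loess_fit(t[1:3], y[1:3]), "4 distinct")
  expect_error(loess_fit(t, y, span = 0.1), "span")
})

test_that("peak calling finds single bumps, biphasic maxima and flat curves", {
  tp <- c(2, 12, 24, 36, 48, 96)
  bump <- function(peak) 1 + 4 * exp(-(log(tp) - log(peak))^2 / 0.3)
  tc <- time_course(rep(tp, each = 3), rep(bump(24), each = 3),
                    B = 500, seed = 1)
  expect_equal(tc$peak$peak_time_h, 24)

  flat <- time_course(rep(tp, each = 3), rep(1, 18), B = 500, seed = 1)
  expect_true(flat$peak$flat)
  expect_true(is.na(flat$peak$peak_time_h))

  bi <- log_bump_vals <- leak <- sapply(tp, cpwave:::leakage_curve)
  tcb <- time_course(rep(tp, each = 3), rep(leak, each = 3), B = 500,
                     seed = 1)
  expect_equal(tcb$peak$local_maxima_h, c(12, 48))
  expect_equal(tcb$peak$peak_time_h, 48)
})

test_that("group summaries obey the boxplot contract", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(4:15, 1), sd = runif(1, 0.5, 4))
    gs <- group_summary(x)
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    expect_equal(c(gs$q1, gs$median, gs$q3), q)
    expect_gte(gs$whisker_lo, min(x))
    expect_lte(gs$whisker_hi, max(x))
    expect_gte(gs$whisker_lo, gs$q1 - 1.5 * (gs$q3 - gs$q1) - 1e-12)
    expect_lte(gs$whisker_hi, gs$q3 + 1.5 * (gs$q3 - gs$q1) + 1e-12)
  }
})

test_that("group comparisons use the exact rank-sum with BH", {
  same <- group_compare(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$tests$p, 1)

  gc <- group_compare(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(gc$tests$p, 0.1)

  expect_message(
    mixed <- group_compare(list(a = 1:5, b = 1:2)),
    "excluded")
  expect_null(mixed$tests)
  expect_equal(nrow(mixed$summary), 2L)
})

test_that("the report writes figures, tables and a manifest", {
  outdir <- withr::local_tempdir()
  # empty results: manifest lists every skipped section, no error
  build_report(list(), outdir)
  manifest <- readLines(file.path(outdir, "manifest.txt"))
  expect_true(any(grepl("sections_skipped=.*leakage_tc", manifest)))

  tp <- c(2, 12, 24, 36, 48, 96)
  tc <- time_course(rep(tp, each = 3),
                    rnorm(18, rep(c(1, 5, 3, 2, 4, 1), each = 3), 0.1),
                    B = 500, seed = 1)
  build_report(list(leakage_tc = tc,
                    dge = data.frame(gene = "g", p = 0.1)), outdir)
  expect_true(file.exists(file.path(outdir, "leakage_tc.csv")))
  expect_true(file.exists(file.path(outdir, "leakage_tc.png")))
  expect_true(file.exists(file.path(outdir, "dge.csv")))

  # rerun determinism: byte-identical CSVs
  f1 <- file.path(outdir, "leakage_tc.csv")
  before <- readLines(f1)
  build_report(list(leakage_tc = tc), outdir)
  expect_identical(readLines(f1), before)
})
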