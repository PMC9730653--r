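# Shared fixtures, built once per test run and memoized. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

test_layout <- function() memo("layout", default_layout())

# the default transcriptomics cohort (6 samples, ~2800 spots)
test_spot_cohort <- function() {
  memo("spot_cohort",
       generate_spot_cohort(test_layout(), default_spot_design(seed = 1)))
}

test_annotation <- function() {
  memo("annotation",
       annotate_spatial(test_spot_cohort(), seed = 1))
}

test_dge <- function() {
  memo("dge", {
    ann <- test_annotation()
    ds <- test_spot_cohort()
    suppressMessages(dge_all_regions(
      ann$normalized, ann$spot_region_coarse,
      ann$normalized$dataset$meta$time_h))
  })
}

# per-section histology tables for the default wildtype time series,
# generated per time point so only one group of images is in memory
test_histology_tables <- function() {
  memo("histology_tables", {
    layout <- test_layout()
    leak <- list(); cd45 <- list(); icam <- list()
    for (tp in c(2, 12, 24, 36, 48, 96)) {
      des <- cohort_design(tp, 3L, "wildtype", seed = 100L + tp)
      secs <- generate_section_cohort(
        layout, des, channels = c("dextran70", "CD45", "ICAM1"))
      leak[[length(leak) + 1L]] <- leakage_table(secs)
      cd45[[length(cd45) + 1L]] <- compartment_table(secs, "CD45")
      icam[[length(icam) + 1L]] <- compartment_table(secs, "ICAM1")
    }
    list(leakage = do.call(rbind, leak), cd45 = do.call(rbind, cd45),
         icam1 = do.call(rbind, icam))
  })
}

test_knockout_tables <- function() {
  memo("knockout_tables", {
    layout <- test_layout()
    kd <- default_knockout_design(seed = 3)
    rows_i <- list(); rows_f <- list()
    for (g in unique(kd$animals$genotype)) {
      sub <- kd
      sub$animals <- kd$animals[kd$animals$genotype == g, ]
      secs <- generate_section_cohort(layout, sub,
                                      channels = c("ICAM1", "F480"))
      rows_i[[g]] <- compartment_table(secs, "ICAM1", "CP_ipsi")
      rows_f[[g]] <- compartment_table(secs, "F480", "CP_ipsi")
    }
    list(ICAM1 = do.call(rbind, rows_i), F480 = do.call(rbind, rows_f))
  })
}

# small two-sample cohort for IO round trips
test_tiny_cohort <- function() {
  memo("tiny_cohort", {
    generate_spot_cohort(test_layout(),
                         cohort_design(c(0, 12), 1L, "wildtype",
                                       seed = 11))
  })
}
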