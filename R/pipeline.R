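#' Run the full analysis pipeline on synthetic cohorts
#'
#' End-to-end run of every stage under one seed: generates the
#' transcriptomics cohort, annotates it (scoring + constrained Leiden +
#' region rule), computes region-stratified differential expression,
#' top-marker tables, gene-set enrichment and the pathway score time
#' course; generates the histology cohort per time point (bounding
#' memory), quantifies leakage and compartment intensities, builds
#' average-intensity maps for the requested map groups; runs the
#' knockout series; and assembles the report.
#'
#' @param outdir report directory.
#' @param config a [run_config()].
#' @param spot_bundle optional directory of an existing spot bundle
#'   (from [write_fixture_bundle()]); by default the cohort is
#'   generated in memory.
#' @param map_markers markers for which average-intensity maps are
#'   written (one map per time point); default ICAM1 only (the most
#'   expensive stage).
#' @return list of all results (as passed to [build_report()]),
#'   invisibly.
#' @export
run_pipeline <- function(outdir, config = run_config(),
                         spot_bundle = NULL, map_markers = "ICAM1") {
  seed <- config$seed
  layout <- default_layout()
  tmpl <- layout_label_image(layout)

  cpw_log("stage 1/4: spatial transcriptomics")
  ds <- if (is.null(spot_bundle)) {
    generate_spot_cohort(layout, cohort_design(config$time_points_h,
                                               1L, "wildtype", seed))
  } else {
    read_spatial_bundle(spot_bundle)
  }
  catalog <- default_marker_sets()
  ann <- annotate_spatial(ds, catalog,
                          target_clusters = config$target_clusters,
                          n_pcs = config$n_pcs,
                          k_neighbors = config$k_neighbors,
                          n_bins = config$n_bins, n_ctrl = config$n_ctrl,
                          dominance_ratio = config$dominance_ratio,
                          seed = seed)
  meta <- ann$normalized$dataset$meta
  regions <- ann$spot_region_coarse
  dge <- dge_all_regions(ann$normalized, regions, meta$time_h)
  topk <- top_k_table(dge, 5L)
  enr_catalog <- gene_set_catalog(
    catalog$sets,
    universe = setdiff(ds$genes, ann$normalized$low_detection),
    provenance = catalog$provenance)
  cp_query <- unique(topk$gene[topk$region == "CP"])
  enrichment <- enrich_hypergeometric(cp_query, enr_catalog)
  score_tc <- gene_set_time_course(
    ann$normalized, catalog$sets$MYD88_TLR_SIGNALING, regions,
    meta$time_h, "CP", n_bins = config$n_bins, n_ctrl = config$n_ctrl,
    seed = seed, level = config$level, B = config$B, span = config$span)

  cpw_log("stage 2/4: histology time series")
  leak_rows <- list(); cd45_rows <- list(); icam_rows <- list()
  maps <- list()
  for (tp in config$histology_time_points_h) {
    des <- cohort_design(tp, config$histology_animals_per_timepoint,
                         "wildtype", child_seed(seed, 100L + tp))
    secs <- generate_section_cohort(layout, des,
                                    channels = config$channels)
    leak_rows[[length(leak_rows) + 1L]] <-
      leakage_table(secs, config$markers$leakage, config$k_sigma)
    cd45_rows[[length(cd45_rows) + 1L]] <-
      compartment_table(secs, config$markers$leukocyte)
    icam_rows[[length(icam_rows) + 1L]] <-
      compartment_table(secs, config$markers$adhesion)
    for (mk in map_markers) {
      maps[[sprintf("%s_t%03d", mk, tp)]] <-
        average_intensity_map(secs, mk, tmpl$labels, tmpl$table)
    }
  }
  leak <- do.call(rbind, leak_rows)
  cd45 <- do.call(rbind, cd45_rows)
  icam <- do.call(rbind, icam_rows)
  leakage_tc <- histology_time_course(leak, "area_mm2",
                                      level = config$level,
                                      B = config$B, span = config$span,
                                      seed = child_seed(seed, 201L))
  cd45_tc <- histology_time_course(
    cd45[cd45$compartment == "CP_ipsi", ], "mean_intensity",
    level = config$level, B = config$B, span = config$span,
    seed = child_seed(seed, 202L))
  icam1_tc <- histology_time_course(
    icam[icam$compartment == "CP_ipsi", ], "mean_intensity",
    level = config$level, B = config$B, span = config$span,
    seed = child_seed(seed, 203L))

  cpw_log("stage 3/4: knockout series")
  ko_rows <- list()
  kd <- default_knockout_design(child_seed(seed, 300L))
  for (g in unique(kd$animals$genotype)) {
    sub <- kd
    sub$animals <- kd$animals[kd$animals$genotype == g, ]
    secs <- generate_section_cohort(layout, sub,
                                    channels = c("ICAM1", "F480"))
    ko_rows[[g]] <- list(
      ICAM1 = compartment_table(secs, "ICAM1", "CP_ipsi"),
      F480 = compartment_table(secs, "F480", "CP_ipsi"))
  }
  knockout <- list(
    ICAM1 = knockout_compare(do.call(rbind,
                                     lapply(ko_rows, `[[`, "ICAM1"))),
    F480 = knockout_compare(do.call(rbind,
                                    lapply(ko_rows, `[[`, "F480"))))

  cpw_log("stage 4/4: report")
  results <- list(
    assignment_table = data.frame(
      barcode = meta$barcode, sample_id = meta$sample_id,
      cluster = ann$clusters, region_label = ann$assignment$spot_region,
      stringsAsFactors = FALSE),
    dge = dge, top_k = topk, enrichment = enrichment,
    score_tc = score_tc, leakage_tc = leakage_tc, cd45_tc = cd45_tc,
    icam1_tc = icam1_tc, knockout = knockout, maps = maps)
  build_report(results, outdir, config)
  invisible(results)
}
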