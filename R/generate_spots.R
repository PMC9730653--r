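#' Generate a synthetic spot-level transcriptomics cohort
#'
#' Draws spot counts for every animal of a cohort design on a shared
#' section layout. Spots sit on a square grid at `pitch_um` spacing
#' (spot diameter recorded in the metadata); each in-tissue spot
#' carries the structure under its center. Counts follow a
#' negative-binomial model: the mean is a log-normal library size times
#' the spot's relative expression, which is the gene's baseline
#' abundance times its anatomical-marker fold (if the spot lies in the
#' marker's region) times the product of all active temporal-program
#' folds at the sample's time point. Ventricle-lumen grid points are
#' emitted in the positions table with `in_tissue = 0` and receive no
#' counts. Fully deterministic given the design seed.
#'
#' @param layout a [section_layout()]; overlapping or empty masks are
#'   rejected.
#' @param design a [cohort_design()].
#' @param programs list of [temporal_program()]s.
#' @param baseline a [default_baseline()]-style table; every scored
#'   region must have at least 5 marker genes.
#' @param pitch_um spot-grid pitch in micrometers.
#' @param spot_diameter_um spot diameter recorded in metadata.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param lib_meanlog,lib_sdlog log-normal library-size parameters.
#' @return a [spatial_dataset()] with a `truth` table (per-spot
#'   structure, region and per-program fold).
#' @export
generate_spot_cohort <- function(layout, design,
                                 programs = default_programs(),
                                 baseline = default_baseline(),
                                 pitch_um = 100, spot_diameter_um = 55,
                                 dispersion = 0.2,
                                 lib_meanlog = 9.2, lib_sdlog = 0.3) {
  validate_layout(layout)
  mk <- table(baseline$marker_region[!is.na(baseline$marker_region)])
  if (any(mk < 5))
    stop("baseline must assign >= 5 marker genes per region")

  pitch_px <- max(1L, round(pitch_um / layout$px_size_um))
  gr <- seq(ceiling(pitch_px / 2), layout$height_px, by = pitch_px)
  gc <- seq(ceiling(pitch_px / 2), layout$width_px, by = pitch_px)
  grid <- expand.grid(array_row = seq_along(gr), array_col = seq_along(gc))
  grid$pxl_row_in_fullres <- gr[grid$array_row]
  grid$pxl_col_in_fullres <- gc[grid$array_col]

  # structure under each grid point (NA outside any mask)
  fine <- rep(NA_character_, nrow(grid))
  for (nm in names(layout$region_masks)) {
    hit <- layout$region_masks[[nm]][cbind(grid$pxl_row_in_fullres,
                                           grid$pxl_col_in_fullres)]
    fine[hit & is.na(fine)] <- nm
  }
  on_section <- !is.na(fine)
  grid <- grid[on_section, ]
  fine <- fine[on_section]
  region <- coarse_region(fine)
  in_tissue <- !is.na(region)
  grid$barcode <- sprintf("BC%05d", seq_len(nrow(grid)))
  grid$in_tissue <- as.integer(in_tissue)

  genes <- baseline$gene
  marker_fold <- attr(baseline, "marker_fold") %||% 8
  deep_fold <- attr(baseline, "deep_fold") %||% 5

  # per-structure anatomical fold vector (time-invariant)
  anat_fold <- function(f) {
    fold <- rep(1, length(genes))
    cr <- coarse_region(f)
    if (is.na(cr)) return(fold)
    if (cr == "DEEP") {
      fold[baseline$marker_region %in% deep_constituents()] <- deep_fold
    } else {
      fold[!is.na(baseline$marker_region) &
             baseline$marker_region == cr] <- marker_fold
    }
    fold
  }
  structures <- unique(fine[in_tissue])
  anat <- vapply(structures, anat_fold, numeric(length(genes)))

  animals <- design$animals
  counts_l <- vector("list", nrow(animals))
  meta_l <- vector("list", nrow(animals))
  pos_l <- vector("list", nrow(animals))
  truth_l <- vector("list", nrow(animals))
  tis <- which(in_tissue)

  for (i in seq_len(nrow(animals))) {
    an <- animals[i, ]
    # per-program fold for each structure at this sample's time
    pf <- vapply(programs, function(p) {
      f <- rep(1, length(structures))
      hit <- program_hits(p, structures)
      f[hit] <- program_fold(p, an$time_h, an$genotype)
      f
    }, numeric(length(structures)))
    if (is.null(dim(pf))) pf <- matrix(pf, nrow = length(structures))
    rownames(pf) <- structures
    colnames(pf) <- vapply(programs, `[[`, character(1), "name")

    rel <- matrix(baseline$base_expr, length(genes), length(tis))
    for (j in seq_along(tis)) {
      st <- fine[tis[j]]
      g_fold <- anat[, st]
      for (k in seq_len(ncol(pf))) {
        if (pf[st, k] != 1) {
          in_prog <- genes %in% programs[[k]]$genes
          g_fold[in_prog] <- g_fold[in_prog] * pf[st, k]
        }
      }
      rel[, j] <- rel[, j] * g_fold
    }
    rel <- sweep(rel, 2, colSums(rel), "/")

    cnt <- with_seed(child_seed(design$seed, i), {
      lib <- rlnorm(length(tis), lib_meanlog, lib_sdlog)
      mu <- sweep(rel, 2, lib, "*")
      matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             nrow = length(genes))
    })
    counts_l[[i]] <- cnt
    meta_l[[i]] <- data.frame(
      barcode = grid$barcode[tis], sample_id = an$sample_id,
      animal = an$animal, time_h = an$time_h, genotype = an$genotype,
      spot_diameter_um = spot_diameter_um, stringsAsFactors = FALSE)
    pos_l[[i]] <- cbind(data.frame(sample_id = an$sample_id), grid)
    truth_l[[i]] <- cbind(
      data.frame(barcode = grid$barcode[tis], sample_id = an$sample_id,
                 structure = fine[tis], region = region[tis],
                 stringsAsFactors = FALSE),
      as.data.frame(pf[fine[tis], , drop = FALSE], row.names = FALSE))
  }

  spatial_dataset(
    counts = Matrix::Matrix(do.call(cbind, counts_l), sparse = TRUE),
    genes = genes,
    positions = do.call(rbind, pos_l),
    meta = do.call(rbind, meta_l),
    truth = do.call(rbind, truth_l),
    px_size_um = layout$px_size_um
  )
}
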