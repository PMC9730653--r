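#' Read a 10x-style spatial bundle
#'
#' Expects `matrix.mtx` (MatrixMarket coordinate, genes x spots),
#' `features.tsv` (id, symbol, type; no header), `barcodes.tsv` and
#' `tissue_positions.csv` in `dir`, plus an optional `metadata.csv`
#' with sample-level fields (sample_id, animal, time_h, genotype).
#' Genes with duplicated symbols are deduplicated (first occurrence
#' wins, logged). Dimension mismatches, malformed headers and barcodes
#' missing from the positions table are specific errors.
#'
#' @param dir bundle directory.
#' @return a [spatial_dataset()].
#' @export
read_spatial_bundle <- function(dir) {
  need <- c("matrix.mtx", "features.tsv", "barcodes.tsv",
            "tissue_positions.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0)
    stop("bundle at '", dir, "' lacks: ", paste(missing, collapse = ", "))

  header <- readLines(file.path(dir, "matrix.mtx"), n = 1)
  if (!grepl("^%%MatrixMarket\\s+matrix\\s+coordinate", header))
    stop("malformed MTX header: ", header)
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(feats) != nrow(counts))
    stop("features.tsv has ", nrow(feats), " rows but matrix has ",
         nrow(counts), " genes")
  if (length(barcodes) != ncol(counts))
    stop("barcodes.tsv has ", length(barcodes), " rows but matrix has ",
         ncol(counts), " spots")
  if (length(barcodes) == 0 || nrow(counts) == 0)
    stop("empty matrix in bundle '", dir, "'")

  symbols <- feats[[min(2, ncol(feats))]]
  dup <- duplicated(symbols)
  if (any(dup)) {
    cpw_log("deduplicating ", sum(dup), " repeated gene symbol(s); ",
            "first occurrence wins")
    counts <- counts[!dup, , drop = FALSE]
    symbols <- symbols[!dup]
  }

  pos <- read.csv(file.path(dir, "tissue_positions.csv"),
                  stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(pos)) pos$sample_id <- "sample1"
  key <- barcodes
  # the positions table stores the composite sample:barcode key
  pos_key <- pos$barcode
  absent <- setdiff(key, pos_key)
  if (length(absent) > 0)
    stop("barcode missing from tissue_positions.csv: ", absent[1])

  meta_path <- file.path(dir, "metadata.csv")
  samples <- sub(":.*$", "", key)
  bare <- sub("^[^:]*:", "", key)
  meta <- data.frame(barcode = bare, sample_id = samples,
                     stringsAsFactors = FALSE)
  if (file.exists(meta_path)) {
    sm <- read.csv(meta_path, stringsAsFactors = FALSE)
    meta <- cbind(meta, sm[match(samples, sm$sample_id),
                           setdiff(names(sm), "sample_id"),
                           drop = FALSE])
    rownames(meta) <- NULL
  } else {
    meta$animal <- samples
    meta$time_h <- NA_real_
    meta$genotype <- NA_character_
  }
  pos$barcode <- sub("^[^:]*:", "", pos$barcode)

  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    read.csv(truth_path, stringsAsFactors = FALSE)
  }
  ds <- spatial_dataset(counts, symbols, pos, meta, truth = NULL)
  if (!is.null(truth)) {
    tkey <- paste(truth$sample_id, truth$barcode, sep = ":")
    ds$truth <- truth[match(colnames(ds$counts), tkey), ]
  }
  ds
}

# integer MatrixMarket coordinate writer (Matrix::writeMM emits
# "real"; 10x bundles use "integer")
write_mtx_integer <- function(m, path) {
  m <- methods::as(m, "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
  writeLines(sprintf("%d %d %d", m@i + 1L, m@j + 1L, as.integer(m@x)),
             con)
}

#' Write a spatial dataset as a 10x-style fixture bundle
#'
#' Emits `matrix.mtx` (integer MatrixMarket), `features.tsv`,
#' `barcodes.tsv`, `tissue_positions.csv`, `metadata.csv`, the planted
#' `truth.csv` when present, and a `gene_sets.gmt` of the supplied
#' catalog. Refuses to write into a non-empty directory unless
#' `force = TRUE`. Round-trips through [read_spatial_bundle()].
#'
#' @param dataset a [spatial_dataset()].
#' @param outdir output directory.
#' @param catalog optional [gene_set_catalog()] to include.
#' @param force overwrite a non-empty directory.
#' @return `outdir`, invisibly.
#' @export
write_fixture_bundle <- function(dataset, outdir, catalog = NULL,
                                 force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force)
    stop("output directory '", outdir,
         "' is not empty; use force = TRUE to overwrite")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  write_mtx_integer(dataset$counts, file.path(outdir, "matrix.mtx"))
  utils::write.table(
    data.frame(id = dataset$genes, symbol = dataset$genes,
               type = "Gene Expression"),
    file.path(outdir, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeLines(colnames(dataset$counts), file.path(outdir, "barcodes.tsv"))

  pos <- dataset$positions
  pos_all <- pos
  pos_all$barcode <- paste(pos_all$sample_id, pos_all$barcode, sep = ":")
  write.csv(pos_all[, c("barcode", "sample_id", "in_tissue", "array_row",
                        "array_col", "pxl_row_in_fullres",
                        "pxl_col_in_fullres")],
            file.path(outdir, "tissue_positions.csv"), row.names = FALSE)

  sm <- unique(dataset$meta[, c("sample_id", "animal", "time_h",
                                "genotype")])
  write.csv(sm, file.path(outdir, "metadata.csv"), row.names = FALSE)
  if (!is.null(dataset$truth))
    write.csv(dataset$truth, file.path(outdir, "truth.csv"),
              row.names = FALSE)
  if (!is.null(catalog))
    write_gmt(catalog, file.path(outdir, "gene_sets.gmt"))
  invisible(outdir)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then members, tab-separated.
#' Trailing tabs (empty member fields) are dropped; duplicate set
#' names are an error.
#'
#' @param path GMT file path.
#' @param universe optional universe; defaults to the union of all
#'   members.
#' @return [read_gmt()]: a [gene_set_catalog()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nms))
    stop("duplicate gene-set names in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "",
                 character(1))
  sets <- lapply(parts, function(p) {
    members <- p[-(1:2)]
    members[nzchar(members)]
  })
  names(sets) <- nms
  gene_set_catalog(sets, universe %||% unique(unlist(sets)),
                   provenance = basename(path),
                   descriptions = setNames(desc, nms))
}

#' @rdname read_gmt
#' @param catalog a [gene_set_catalog()].
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog$sets), function(nm) {
    paste(c(nm, catalog$descriptions[[nm]] %||% "",
            catalog$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# label images are written as 16-bit TIFF (labels / 65535) with a
# sidecar CSV label table
write_label_tiff <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
}

read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Read a label-mask TIFF with its label table
#'
#' @param tiff_path unsigned-integer label image (0 = background).
#' @param table_path CSV with columns label, compartment, hemisphere.
#' @return list with `labels` (integer matrix) and `table`.
#' @export
read_masks <- function(tiff_path, table_path) {
  labels <- read_label_tiff(tiff_path)
  tab <- read.csv(table_path, stringsAsFactors = FALSE)
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(present, tab$label)
  if (length(unknown) > 0)
    stop("label(s) in mask image absent from label table: ",
         paste(unknown, collapse = ", "))
  list(labels = labels, table = tab)
}

intensity_scale <- 65535

#' Write / read a section image directory
#'
#' One directory per section: each channel as 16-bit grayscale TIFF,
#' the compartment mask as label TIFF + `labels.csv`, the hemisphere
#' mask as label TIFF, and the metadata as `meta.yaml`.
#'
#' @param section a [section_image()].
#' @param dir target directory.
#' @export
write_section_image <- function(section, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in names(section$channels)) {
    img <- pmin(section$channels[[ch]], intensity_scale) /
      intensity_scale
    tiff::writeTIFF(img, file.path(dir, paste0(ch, ".tiff")),
                    bits.per.sample = 16L)
  }
  write_label_tiff(section$mask, file.path(dir, "mask.tiff"))
  write_label_tiff(section$hemispheres, file.path(dir, "hemi.tiff"))
  write.csv(section$label_table, file.path(dir, "labels.csv"),
            row.names = FALSE)
  yaml::write_yaml(
    list(px_size_um = section$px_size_um,
         section_position_um = section$section_position_um,
         animal = section$animal, time_h = section$time_h,
         genotype = section$genotype,
         channels = names(section$channels)),
    file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_section_image
#' @export
read_section_image <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  masks <- read_masks(file.path(dir, "mask.tiff"),
                      file.path(dir, "labels.csv"))
  hemi <- read_label_tiff(file.path(dir, "hemi.tiff"))
  channels <- lapply(meta$channels, function(ch) {
    m <- tiff::readTIFF(file.path(dir, paste0(ch, ".tiff")))
    m * intensity_scale
  })
  names(channels) <- meta$channels
  section_image(channels, masks$labels, masks$table, hemi,
                meta$px_size_um, meta$section_position_um, meta$animal,
                meta$time_h, meta$genotype)
}

#' Write / read an average-intensity map
#'
#' The map is stored as 32-bit float TIFF. TIFF stores samples on
#' [0, 1], so intensities are divided by their maximum, which is
#' recorded in a sidecar YAML together with the marker and group
#' sizes; off-coverage (`NA`) pixels are encoded through the coverage
#' counts, written as a sibling 16-bit TIFF. [read_intensity_map()]
#' reverses all of this exactly.
#'
#' @param map an `intensity_map` from [average_intensity_map()].
#' @param path output TIFF path (coverage and sidecar written next to
#'   it).
#' @export
write_intensity_map <- function(map, path) {
  scale <- max(map$map[is.finite(map$map)], 1e-12)
  m <- map$map / scale
  m[!is.finite(m)] <- 0
  tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = TRUE)
  write_label_tiff(map$coverage,
                   sub("\\.tiff?$", "_coverage.tiff", path))
  yaml::write_yaml(list(scale = scale, marker = map$marker,
                        n_sections = map$n_sections,
                        n_animals = map$n_animals),
                   sub("\\.tiff?$", "_meta.yaml", path))
  invisible(path)
}

#' @rdname write_intensity_map
#' @export
read_intensity_map <- function(path) {
  meta <- yaml::read_yaml(sub("\\.tiff?$", "_meta.yaml", path))
  m <- tiff::readTIFF(path) * meta$scale
  cov <- read_label_tiff(sub("\\.tiff?$", "_coverage.tiff", path))
  m[cov == 0L] <- NA_real_
  structure(list(map = m, coverage = cov,
                 n_sections = meta$n_sections,
                 n_animals = meta$n_animals, marker = meta$marker,
                 residuals = NULL),
            class = "intensity_map")
}

#' Pipeline run configuration
#'
#' All stage parameters with their package defaults; round-trips
#' losslessly through YAML.
#'
#' @param ... overrides of the default fields.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_pcs = 30L, k_neighbors = 15L, target_clusters = 5L,
    n_bins = 25L, n_ctrl = 50L, dominance_ratio = 0.75,
    k_sigma = 3, span = 0.5, B = 10000L, level = 0.95,
    time_points_h = c(0, 2, 12, 24, 48, 96),
    histology_time_points_h = c(2, 12, 24, 36, 48, 96),
    histology_animals_per_timepoint = 3L,
    channels = c("dextran70", "CD45", "ICAM1"),
    markers = list(leakage = "dextran70", leukocyte = "CD45",
                   adhesion = "ICAM1")
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0)
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  structure(modifyList(cfg, over), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
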