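#' Spatial transcriptomics dataset
#'
#' Spot-level counts with spatial positions and per-spot sample
#' metadata, possibly spanning several samples (sections). Counts are
#' stored features-in-rows (genes x spots) as a sparse matrix, the
#' convention of the R single-cell ecosystem; spot columns are keyed by
#' `sample_id:barcode`, unique across the dataset, while barcodes are
#' only required to be unique within a sample.
#'
#' @param counts genes x spots matrix (coerced to sparse `dgCMatrix`)
#'   of non-negative integers.
#' @param genes character vector of gene symbols (rownames).
#' @param positions data.frame with columns barcode, sample_id,
#'   in_tissue, array_row, array_col, pxl_row_in_fullres,
#'   pxl_col_in_fullres.
#' @param meta data.frame with columns barcode, sample_id, animal,
#'   time_h, genotype; one row per spot, aligned with `counts` columns.
#' @param truth optional data.frame of planted ground truth (columns
#'   barcode, sample_id, structure, region and one fold column per
#'   program).
#' @param px_size_um physical pixel size of the position coordinates.
#' @return object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(counts, genes, positions, meta, truth = NULL,
                            px_size_um = 20) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  if (length(genes) != nrow(counts))
    stop("length(genes) != nrow(counts)")
  if (nrow(meta) != ncol(counts))
    stop("nrow(meta) != ncol(counts)")
  v <- counts@x
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("counts must be finite non-negative integers")
  key <- paste(meta$sample_id, meta$barcode, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate barcodes within a sample: ",
         paste(head(key[duplicated(key)], 3), collapse = ", "))
  pos_key <- paste(positions$sample_id, positions$barcode, sep = ":")
  missing_pos <- setdiff(key, pos_key)
  if (length(missing_pos) > 0)
    stop("spot without a position: ", head(missing_pos, 1))
  rownames(counts) <- genes
  colnames(counts) <- key
  positions <- positions[match(key, pos_key), ]
  structure(
    list(counts = counts, genes = genes, positions = positions,
         meta = meta, truth = truth, px_size_um = px_size_um),
    class = "spatial_dataset"
  )
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d genes x %d spots, %d sample(s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$meta$sample_id))))
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$counts)

#' Subset a spatial dataset by spot index
#'
#' @param dataset a [spatial_dataset()].
#' @param spots logical or integer index over spot columns.
#' @return the subsetted [spatial_dataset()].
#' @export
subset_spots <- function(dataset, spots) {
  truth <- if (!is.null(dataset$truth)) dataset$truth[spots, , drop = FALSE]
  spatial_dataset(dataset$counts[, spots, drop = FALSE], dataset$genes,
                  dataset$positions[spots, , drop = FALSE],
                  dataset$meta[spots, , drop = FALSE], truth,
                  dataset$px_size_um)
}

#' Median-scale log-normalize spot counts
#'
#' Each spot's counts are scaled to the median total count across spots
#' and transformed with `log(1 + x)`. Spots with zero total count are
#' dropped with a warning. Genes detected in fewer than `min_spots`
#' spots are flagged in the `low_detection` attribute but retained; the
#' same threshold defines the enrichment universe downstream.
#'
#' @param dataset a [spatial_dataset()].
#' @param min_spots detection threshold for the `low_detection` flag.
#' @return list with `expr` (dense genes x spots matrix of
#'   log-normalized values), `dataset` (possibly spot-filtered input),
#'   `size_factors`, and `detected` (per-gene number of spots with a
#'   nonzero count). Class `normalized_expr`.
#' @export
normalize_counts <- function(dataset, min_spots = 3L) {
  totals <- Matrix::colSums(dataset$counts)
  if (any(totals == 0)) {
    cpw_warn(sum(totals == 0), " spot(s) with zero total count dropped")
    dataset <- subset_spots(dataset, totals > 0)
    totals <- totals[totals > 0]
  }
  med <- median(totals)
  sf <- totals / med
  expr <- as.matrix(dataset$counts %*% Matrix::Diagonal(x = 1 / sf))
  colnames(expr) <- colnames(dataset$counts)
  expr <- log1p(expr)
  detected <- Matrix::rowSums(dataset$counts > 0)
  structure(
    list(expr = expr, dataset = dataset, size_factors = sf,
         detected = detected,
         low_detection = dataset$genes[detected < min_spots]),
    class = "normalized_expr"
  )
}
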