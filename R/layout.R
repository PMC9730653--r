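#' Section layout: a stylized coronal section template
#'
#' A `section_layout` holds a pixel template of a coronal mouse-brain
#' section with disjoint binary masks for the anatomical structures the
#' analysis distinguishes: cortex (CTX), striatum (ipsi/contralateral to
#' the injection), thalamus (TH), deep-brain structures (DEEP, the
#' pallidum/hypothalamus/midbrain/pons territory), the striatal lesion,
#' the three ventricles and the choroid plexus (CP) inside each
#' ventricle. The lesion is carved out of the ipsilateral striatum and
#' each CP out of its ventricle, so masks are mutually disjoint while
#' the anatomical containments (lesion in striatum, CP in ventricle)
#' hold for the underlying territories.
#'
#' @param width_px,height_px template size in pixels.
#' @param px_size_um physical pixel size, micrometers per pixel.
#' @param region_masks named list of logical matrices
#'   (`height_px x width_px`), mutually disjoint.
#' @param outline logical matrix, the section outline (all masks lie
#'   inside it).
#' @return an object of class `section_layout`.
#' @seealso [default_layout()]
#' @export
section_layout <- function(width_px, height_px, px_size_um, region_masks,
                           outline) {
  stopifnot(is.list(region_masks), length(region_masks) > 0,
            !is.null(names(region_masks)), px_size_um > 0)
  dims <- c(height_px, width_px)
  for (nm in names(region_masks)) {
    m <- region_masks[[nm]]
    if (!is.logical(m) || !all(dim(m) == dims))
      stop("mask '", nm, "' must be a logical ", height_px, "x", width_px,
           " matrix")
  }
  x <- structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         px_size_um = px_size_um, region_masks = region_masks,
         outline = outline),
    class = "section_layout"
  )
  validate_layout(x)
  x
}

#' @export
print.section_layout <- function(x, ...) {
  cat(sprintf("section_layout: %dx%d px at %.1f um/px\n",
              x$height_px, x$width_px, x$px_size_um))
  px <- vapply(x$region_masks, sum, numeric(1))
  for (nm in names(px)) cat(sprintf("  %-16s %6d px\n", nm, px[[nm]]))
  invisible(x)
}

# disjointness, containment-in-outline, and territory containment
# (lesion in striatum, CP in ventricle) checks; stops on violation
validate_layout <- function(layout) {
  masks <- layout$region_masks
  stack <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(stack > 1L)) stop("region masks overlap")
  if (any(stack == 1L & !layout$outline))
    stop("region masks extend outside the section outline")
  if (any(vapply(masks, sum, numeric(1)) == 0)) stop("empty region mask")
  contain <- list(
    c("lesion", "STR_ipsi"),
    c("CP_ipsi", "ventricle_ipsi"),
    c("CP_contra", "ventricle_contra"),
    c("CP_third", "ventricle_third")
  )
  for (p in contain) {
    if (!all(p %in% names(masks))) next
    ring <- dilate1(masks[[p[1]]]) & !masks[[p[1]]]
    if (!all(masks[[p[2]]][ring] | masks[[p[1]]][ring]))
      stop("'", p[1], "' is not contained in the '", p[2], "' territory")
  }
  invisible(TRUE)
}

# one-pixel 8-neighborhood dilation, used only for containment checks
dilate1 <- function(m) {
  n <- m
  nr <- nrow(m); nc <- ncol(m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    src_r <- max(1, 1 - dr):min(nr, nr - dr)
    dst_r <- src_r + dr
    src_c <- max(1, 1 - dc):min(nc, nc - dc)
    dst_c <- src_c + dc
    n[dst_r, dst_c] <- n[dst_r, dst_c] | m[src_r, src_c]
  }
  n
}

ellipse_mask <- function(nr, nc, center, semi) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((r - center[1]) / semi[1])^2 + ((c - center[2]) / semi[2])^2 <= 1
}

disc_mask <- function(nr, nc, center, radius) {
  ellipse_mask(nr, nc, center, c(radius, radius))
}

#' Default section layout
#'
#' A 512x512 template at 20 um/px. The section is a stylized ellipse:
#' an outer cortical band, lateral striatal blocks (with the lesion in
#' the ipsilateral one; ipsilateral = left half), a central thalamic
#' block containing the third ventricle, a ventral deep-brain block,
#' and lateral/third ventricles each containing a choroid plexus. The
#' geometry is sized so that a 100 um spot grid yields roughly 500
#' in-tissue spots; it is a statistical stand-in, not an atlas.
#'
#' @param width_px,height_px,px_size_um template geometry.
#' @return a [section_layout()].
#' @export
default_layout <- function(width_px = 512L, height_px = 512L,
                           px_size_um = 20) {
  nr <- height_px; nc <- width_px
  ctr <- c(nr, nc) / 2
  semi <- c(45, 88) * (c(nr, nc) / 512)

  rnorm2 <- {
    r <- matrix(seq_len(nr), nr, nc)
    c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    ((r - ctr[1]) / semi[1])^2 + ((c - ctr[2]) / semi[2])^2
  }
  outline <- rnorm2 <= 1
  interior <- rnorm2 <= 0.72^2
  ctx <- outline & !interior

  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  vent_ipsi_t <- ellipse_mask(nr, nc, ctr + c(-16, -28), c(16, 11))
  vent_contra_t <- ellipse_mask(nr, nc, ctr + c(-16, 28), c(16, 11))
  vent_third_t <- ellipse_mask(nr, nc, ctr + c(-16, 0), c(10, 6))
  cp_ipsi <- disc_mask(nr, nc, ctr + c(-16, -28), 8)
  cp_contra <- disc_mask(nr, nc, ctr + c(-16, 28), 8)
  cp_third <- disc_mask(nr, nc, ctr + c(-16, 0), 4)
  lesion <- disc_mask(nr, nc, ctr + c(-4, -52), 6)

  deep <- interior & rr >= ctr[1] + 14
  th_block <- interior & rr < ctr[1] + 14 & abs(cc - ctr[2]) <= 30
  str_block <- interior & rr < ctr[1] + 14 & abs(cc - ctr[2]) > 30

  vent_all <- vent_ipsi_t | vent_contra_t | vent_third_t
  th <- th_block & !vent_all
  str_ipsi <- str_block & cc < ctr[2] & !vent_all & !lesion
  str_contra <- str_block & cc >= ctr[2] & !vent_all
  deep <- deep & !vent_all

  masks <- list(
    CTX = ctx & !vent_all,
    STR_ipsi = str_ipsi, STR_contra = str_contra,
    TH = th, DEEP = deep, lesion = lesion,
    ventricle_ipsi = vent_ipsi_t & !cp_ipsi,
    ventricle_contra = vent_contra_t & !cp_contra,
    ventricle_third = vent_third_t & !cp_third,
    CP_ipsi = cp_ipsi, CP_contra = cp_contra, CP_third = cp_third
  )
  section_layout(width_px, height_px, px_size_um, masks, outline)
}

# fine structure label -> coarse anatomical region used by the
# transcriptomics truth and the region score sets
coarse_region <- function(fine) {
  map <- c(
    CTX = "CTX", STR_ipsi = "STR", STR_contra = "STR", TH = "TH",
    DEEP = "DEEP", lesion = "STR",
    ventricle_ipsi = NA, ventricle_contra = NA, ventricle_third = NA,
    CP_ipsi = "CP", CP_contra = "CP", CP_third = "CP"
  )
  unname(map[fine])
}

# the four deep-brain constituents scored separately during annotation
deep_constituents <- function() c("PAL", "HY", "MB", "P")

anatomical_regions <- function() {
  c("CTX", "STR", "TH", "CP", deep_constituents())
}

#' Integer label image and label table for a layout
#'
#' Collapses the layout's binary masks into a single label image
#' (0 = background) plus a table mapping labels to structure names and
#' hemispheres, the representation used for section-image masks.
#'
#' @param layout a [section_layout()].
#' @return list with `labels` (integer matrix), `table` (data.frame:
#'   label, compartment, hemisphere), and `hemispheres` (integer matrix,
#'   0 background / 1 ipsilateral / 2 contralateral).
#' @export
layout_label_image <- function(layout) {
  nms <- names(layout$region_masks)
  lab <- matrix(0L, layout$height_px, layout$width_px)
  for (i in seq_along(nms)) lab[layout$region_masks[[nms[i]]]] <- i
  hemi_of <- function(nm) {
    if (grepl("ipsi$|lesion", nm)) "ipsi"
    else if (grepl("contra$", nm)) "contra"
    else "mid"
  }
  tab <- data.frame(
    label = seq_along(nms), compartment = nms,
    hemisphere = vapply(nms, hemi_of, character(1)),
    stringsAsFactors = FALSE
  )
  cc <- matrix(seq_len(layout$width_px), layout$height_px,
               layout$width_px, byrow = TRUE)
  hemi <- matrix(0L, layout$height_px, layout$width_px)
  hemi[layout$outline & cc < layout$width_px / 2] <- 1L
  hemi[layout$outline & cc >= layout$width_px / 2] <- 2L
  list(labels = lab, table = tab, hemispheres = hemi)
}
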