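#' Standardized section selection
#'
#' Implements the standardized eight-section rule: starting from the
#' first section at or beyond `start_um` (positions in micrometers
#' posterior to the anterior commissure, sorted ascending), every
#' `step_sections`-th section is taken until `n_sections` are
#' selected.
#'
#' @param positions_um sorted ascending section positions.
#' @param start_um selection start (300 um in the standard rule).
#' @param step_sections take every this-many-th section (2 = every
#'   second).
#' @param n_sections number of sections to select (8).
#' @return integer indices into `positions_um` (1-based).
#' @export
select_standard_sections <- function(positions_um, start_um = 300,
                                     step_sections = 2L,
                                     n_sections = 8L) {
  if (is.unsorted(positions_um))
    stop("section positions must be sorted ascending")
  first <- which(positions_um >= start_um)[1]
  if (is.na(first))
    stop("no section at or beyond ", start_um, " um")
  idx <- seq(first, by = step_sections, length.out = n_sections)
  if (max(idx) > length(positions_um)) {
    need <- max(idx)
    stop("stack too short: selection needs ", need,
         " sections from the start index but only ",
         length(positions_um), " are available (short by ",
         need - length(positions_um), ")")
  }
  idx
}

#' Cross-animal average-intensity map
#'
#' The quantitative summary of fluorophore accumulation for one marker
#' in one (time, genotype) group: every section is normalized by its
#' contralateral-hemisphere median, registered to the template by
#' [estimate_registration()], warped with bilinear interpolation, and
#' the per-pixel mean over all contributing sections is returned on
#' the coverage mask (pixels seen by at least one section; missing
#' pixels are excluded from the mean, not zero-filled).
#'
#' @param sections list of [section_image()]s (one group).
#' @param marker channel name.
#' @param template_mask,template_table template label image and table
#'   (e.g. from [layout_label_image()]).
#' @param normalize divide each section by its contralateral
#'   hemisphere median first (default TRUE).
#' @return object of class `intensity_map`: list with `map` (numeric
#'   matrix, `NA` off coverage), `coverage` (integer contribution
#'   counts), `n_sections`, `n_animals`, `residuals`.
#' @export
average_intensity_map <- function(sections, marker, template_mask,
                                  template_table, normalize = TRUE) {
  if (length(sections) == 0) stop("no sections in group")
  shape <- dim(template_mask)
  acc <- matrix(0, shape[1], shape[2])
  cnt <- matrix(0L, shape[1], shape[2])
  residuals <- numeric(length(sections))
  for (i in seq_along(sections)) {
    s <- sections[[i]]
    img <- if (normalize) normalize_section(s, marker)
           else s$channels[[marker]]
    if (is.null(img)) stop("section ", i, " lacks channel '", marker, "'")
    tr <- estimate_registration(s$mask, template_mask, s$label_table,
                                template_table)
    residuals[i] <- attr(tr, "residual")
    w <- warp_to_template(img, tr, shape, "bilinear")
    seen <- !is.na(w)
    acc[seen] <- acc[seen] + w[seen]
    cnt <- cnt + seen
  }
  map <- acc / cnt
  map[cnt == 0L] <- NA_real_
  structure(
    list(map = map, coverage = cnt, n_sections = length(sections),
         n_animals = length(unique(vapply(sections, `[[`, character(1),
                                          "animal"))),
         marker = marker, residuals = residuals),
    class = "intensity_map"
  )
}

#' @export
print.intensity_map <- function(x, ...) {
  cat(sprintf("intensity_map (%s): %d sections / %d animals, coverage %.0f%%\n",
              x$marker, x$n_sections, x$n_animals,
              100 * mean(x$coverage > 0)))
  invisible(x)
}

# 8-connected component labeling of a logical matrix; returns an
# integer matrix (0 outside the mask)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(matrix(0L, nr, nc))
  pos <- match(seq_len(nr * nc), idx)  # linear index -> vertex id
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  edges <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + d[1]; c2 <- c + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    lin2 <- (c2[ok] - 1L) * nr + r2[ok]
    v2 <- pos[lin2]
    keep <- !is.na(v2)
    edges <- rbind(edges, cbind(which(ok)[keep], v2[keep]))
  }
  comp <- if (is.null(edges) || nrow(edges) == 0) {
    seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) -
                                       igraph::vcount(g)))
    igraph::components(g)$membership
  }
  out <- matrix(0L, nr, nc)
  out[idx] <- as.integer(comp)
  out
}

#' Quantify dextran leakage area and intensity
#'
#' Semi-automated leakage quantification made fully automatic: the
#' threshold is the background mean plus `k_sigma` background standard
#' deviations; supra-threshold pixels are grouped into 8-connected
#' components; the leakage is the union of components intersecting a
#' `site_radius_um` disc around the injection site. Its area is the
#' pixel count times the pixel area; its mean intensity is averaged
#' over the component pixels. With no supra-threshold component near
#' the site the area is 0 and the intensity missing.
#'
#' @param image numeric intensity matrix.
#' @param injection_site_px numeric `(row, col)` of the injection site.
#' @param background_mask logical matrix of background (reference)
#'   pixels, disjoint from the expected leakage.
#' @param k_sigma threshold stringency.
#' @param px_size_um pixel size.
#' @param site_radius_um radius of the site disc (200 um).
#' @return list with `area_mm2`, `mean_intensity` (`NA` when absent),
#'   `threshold`, `n_components`.
#' @export
quantify_leakage <- function(image, injection_site_px, background_mask,
                             k_sigma = 3, px_size_um = 20,
                             site_radius_um = 200) {
  bg <- image[background_mask]
  if (length(bg) < 2) stop("background mask too small")
  thr <- mean(bg) + k_sigma * sd(bg)
  supra <- image > thr
  comps <- label_components(supra)
  rr <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
  cc <- matrix(seq_len(ncol(image)), nrow(image), ncol(image),
               byrow = TRUE)
  site_r_px <- site_radius_um / px_size_um
  near <- (rr - injection_site_px[1])^2 +
    (cc - injection_site_px[2])^2 <= site_r_px^2
  hit <- setdiff(unique(comps[near & supra]), 0L)
  if (length(hit) == 0) {
    return(list(area_mm2 = 0, mean_intensity = NA_real_,
                threshold = thr, n_components = max(comps)))
  }
  sel <- comps %in% hit
  px_area_mm2 <- (px_size_um / 1000)^2
  list(area_mm2 = sum(sel) * px_area_mm2,
       mean_intensity = mean(image[sel]),
       threshold = thr, n_components = max(comps))
}

#' Per-compartment mean intensity
#'
#' Mean of a section channel (by default normalized by the
#' contralateral-hemisphere median) over the pixels of each requested
#' compartment. Empty compartments yield `NA` with a warning.
#'
#' @param section a [section_image()].
#' @param channel channel name.
#' @param compartments compartment names from the label table;
#'   defaults to all.
#' @param normalize use [normalize_section()] first.
#' @return named numeric vector of means.
#' @export
compartment_mean_intensity <- function(section, channel,
                                       compartments = NULL,
                                       normalize = TRUE) {
  img <- if (normalize) normalize_section(section, channel)
         else section$channels[[channel]]
  if (is.null(img)) stop("unknown channel '", channel, "'")
  compartments <- compartments %||%
    unique(section$label_table$compartment)
  out <- vapply(compartments, function(cmp) {
    px <- compartment_pixels(section, cmp)
    if (!any(px)) {
      cpw_warn("compartment '", cmp, "' is empty in this section")
      return(NA_real_)
    }
    mean(img[px])
  }, numeric(1))
  names(out) <- compartments
  out
}
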