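#' Multichannel section image
#'
#' One histological section: named intensity channels, a compartment
#' label image with its label table, a hemisphere label image
#' (1 = ipsilateral, 2 = contralateral), the physical pixel size, the
#' section position along the stack (micrometers posterior to the
#' anterior commissure, positive posterior) and the animal metadata.
#'
#' @param channels named list of numeric matrices, all the same size.
#' @param mask integer label image (0 = background).
#' @param label_table data.frame (label, compartment, hemisphere)
#'   covering every nonzero label in `mask`.
#' @param hemispheres integer matrix (0/1/2).
#' @param px_size_um micrometers per pixel, > 0.
#' @param section_position_um stack position.
#' @param animal,time_h,genotype sample metadata.
#' @param truth optional list of planted ground truth (pose transform,
#'   leakage geometry, channel means).
#' @return object of class `section_image`.
#' @export
section_image <- function(channels, mask, label_table, hemispheres,
                          px_size_um, section_position_um,
                          animal, time_h, genotype, truth = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), px_size_um > 0)
  dims <- dim(mask)
  for (nm in names(channels)) {
    if (!all(dim(channels[[nm]]) == dims))
      stop("channel '", nm, "' does not match the mask dimensions")
  }
  present <- setdiff(unique(as.vector(mask)), 0L)
  uncovered <- setdiff(present, label_table$label)
  if (length(uncovered) > 0)
    stop("mask label(s) missing from the label table: ",
         paste(uncovered, collapse = ", "))
  structure(
    list(channels = channels, mask = mask, label_table = label_table,
         hemispheres = hemispheres, px_size_um = px_size_um,
         section_position_um = section_position_um, animal = animal,
         time_h = time_h, genotype = genotype, truth = truth),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf(
    "section_image: %dx%d px, channels [%s], %s %gh %s, position %g um\n",
    nrow(x$mask), ncol(x$mask), paste(names(x$channels), collapse = ", "),
    x$animal, x$time_h, x$genotype, x$section_position_um))
  invisible(x)
}

# pixels of one named compartment
compartment_pixels <- function(section, compartment) {
  lab <- section$label_table$label[
    section$label_table$compartment == compartment]
  if (length(lab) == 0) return(logical(length(section$mask)))
  section$mask %in% lab
}

#' Normalize a section channel by the contralateral hemisphere
#'
#' Divides the channel by the median intensity over the contralateral
#' hemisphere, the per-section intensity calibration used before
#' averaging across sections and animals.
#'
#' @param section a [section_image()].
#' @param channel channel name.
#' @return numeric matrix of normalized intensities.
#' @export
normalize_section <- function(section, channel) {
  img <- section$channels[[channel]]
  if (is.null(img)) stop("unknown channel '", channel, "'")
  ref <- median(img[section$hemispheres == 2L])
  if (!is.finite(ref) || ref <= 0)
    stop("contralateral-hemisphere reference is not positive")
  img / ref
}
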