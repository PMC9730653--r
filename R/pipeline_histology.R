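section_compartment_centroid <- function(section, compartment) {
  px <- compartment_pixels(section, compartment)
  if (!any(px)) stop("compartment '", compartment, "' empty")
  colMeans(which(matrix(px, nrow(section$mask)), arr.ind = TRUE))
}

#' Leakage area/intensity per section
#'
#' Runs [quantify_leakage()] on every section of a cohort: the
#' injection site is the centroid of the section's own lesion label,
#' the background reference the contralateral striatum.
#'
#' @param sections list of [section_image()]s.
#' @param marker dextran channel name.
#' @param k_sigma threshold stringency.
#' @return data.frame (animal, time_h, genotype, section_position_um,
#'   area_mm2, mean_intensity).
#' @export
leakage_table <- function(sections, marker = "dextran70", k_sigma = 3) {
  do.call(rbind, lapply(sections, function(s) {
    site <- section_compartment_centroid(s, "lesion")
    bg <- compartment_pixels(s, "STR_contra")
    lk <- quantify_leakage(s$channels[[marker]], site,
                           matrix(bg, nrow(s$mask)), k_sigma,
                           s$px_size_um)
    data.frame(animal = s$animal, time_h = s$time_h,
               genotype = s$genotype,
               section_position_um = s$section_position_um,
               area_mm2 = lk$area_mm2,
               mean_intensity = lk$mean_intensity,
               stringsAsFactors = FALSE)
  }))
}

#' Per-section compartment intensity table
#'
#' [compartment_mean_intensity()] (contralateral-hemisphere
#' normalized) for every section, long format.
#'
#' @param sections list of [section_image()]s.
#' @param marker channel name.
#' @param compartments compartments to summarise.
#' @return data.frame (animal, time_h, genotype, compartment,
#'   mean_intensity).
#' @export
compartment_table <- function(sections, marker,
                              compartments = c("CP_ipsi", "CP_contra",
                                               "CP_third", "STR_ipsi",
                                               "STR_contra")) {
  do.call(rbind, lapply(sections, function(s) {
    m <- compartment_mean_intensity(s, marker, compartments)
    data.frame(animal = s$animal, time_h = s$time_h,
               genotype = s$genotype, compartment = names(m),
               mean_intensity = unname(m), stringsAsFactors = FALSE)
  }))
}

# collapse a per-section table to animal level (sections averaged
# within animal first), keeping time/genotype metadata
animal_means <- function(df, value_col) {
  agg <- aggregate(df[[value_col]],
                   list(animal = df$animal, time_h = df$time_h,
                        genotype = df$genotype),
                   mean, na.rm = TRUE)
  names(agg)[4] <- value_col
  agg
}

#' Animal-level time course of a per-section quantity
#'
#' Sections are averaged within animal, then the animal-level values
#' per time point are summarised with [time_course()] (mean, bootstrap
#' CI, loess, peak call).
#'
#' @param df per-section table ([leakage_table()] or
#'   [compartment_table()], the latter filtered to one compartment).
#' @param value_col value column name.
#' @param level,B,span,seed [time_course()] parameters.
#' @return a `time_course`.
#' @export
histology_time_course <- function(df, value_col, level = 0.95,
                                  B = 10000L, span = 0.5, seed = 1L) {
  am <- animal_means(df, value_col)
  time_course(am$time_h, am[[value_col]], level = level, B = B,
              span = span, seed = seed, log_time = TRUE)
}

#' Knockout-series comparison of a compartment marker
#'
#' Animal-level means per genotype group at a single time point,
#' summarised and tested with [group_compare()]: the standard family
#' compares wildtype against each knockout and against sham.
#'
#' @param df per-section [compartment_table()] filtered to one
#'   compartment.
#' @param value_col value column.
#' @param reference the blood-injected wildtype group label.
#' @return [group_compare()] output.
#' @export
knockout_compare <- function(df, value_col = "mean_intensity",
                             reference = "wildtype") {
  am <- animal_means(df, value_col)
  values <- split(am[[value_col]], am$genotype)
  others <- setdiff(names(values), reference)
  pairs <- lapply(others, function(g) c(reference, g))
  # knockouts are also compared to sham to show equivalence
  if ("sham" %in% others) {
    for (g in setdiff(others, "sham"))
      pairs[[length(pairs) + 1L]] <- c(g, "sham")
  }
  group_compare(values, pairs)
}
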