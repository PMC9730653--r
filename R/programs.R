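#' Temporal expression/intensity program
#'
#' A program is a multiplicative, compartment-restricted fold-change
#' with a unimodal (or biphasic) bump in log-time. At time `t` hours the
#' fold is `1 + (amplitude - 1) * exp(-(log t - log peak)^2 / (2 w^2))`,
#' plus a second bump for biphasic programs; at the uninjected control
#' (t = 0) the fold is exactly 1. Programs are classed as `"blood"`
#' (direct consequence of the injected blood, e.g. the erythrocyte
#' transcript pulse) or `"inflammatory"` (host response): sham animals
#' (saline injection) silence both classes, TLR4/MyD88 knockouts
#' silence inflammatory programs in the choroid plexus only.
#'
#' @param name program identifier.
#' @param genes character vector of gene symbols (ignored for imaging
#'   channels).
#' @param compartment one of CTX, STR, TH, CP, DEEP, lesion.
#' @param peak_time_h peak time in hours, one of 2, 12, 24, 36, 48, 96.
#' @param amplitude multiplicative fold at the peak, >= 1.
#' @param width kernel width (sd of the log-time Gaussian bump).
#' @param peak2_time_h,peak2_amplitude optional second bump (biphasic).
#' @param class `"inflammatory"` or `"blood"`.
#' @return object of class `temporal_program`.
#' @export
temporal_program <- function(name, genes, compartment, peak_time_h,
                             amplitude, width = 0.35,
                             peak2_time_h = NULL, peak2_amplitude = NULL,
                             class = c("inflammatory", "blood")) {
  class <- match.arg(class)
  allowed_t <- c(2, 12, 24, 36, 48, 96)
  stopifnot(amplitude >= 1, peak_time_h %in% allowed_t, width > 0,
            compartment %in% c("CTX", "STR", "TH", "CP", "DEEP", "lesion"))
  if (!is.null(peak2_time_h)) {
    stopifnot(peak2_time_h %in% allowed_t, peak2_amplitude >= 1)
  }
  structure(
    list(name = name, genes = genes, compartment = compartment,
         peak_time_h = peak_time_h, amplitude = amplitude, width = width,
         peak2_time_h = peak2_time_h, peak2_amplitude = peak2_amplitude,
         program_class = class),
    class = "temporal_program"
  )
}

log_bump <- function(time_h, peak_h, width) {
  out <- numeric(length(time_h))
  pos <- time_h > 0
  out[pos] <- exp(-(log(time_h[pos]) - log(peak_h))^2 / (2 * width^2))
  out
}

#' Evaluate a program's fold-change at given times
#'
#' @param program a [temporal_program()].
#' @param time_h numeric hours; 0 denotes the uninjected control
#'   (fold 1).
#' @param genotype genotype of the animal; sham silences every program,
#'   knockouts silence inflammatory choroid-plexus programs.
#' @return numeric fold >= 1, same length as `time_h`.
#' @export
program_fold <- function(program, time_h,
                         genotype = "wildtype") {
  if (program_silenced(program, genotype)) return(rep(1, length(time_h)))
  f <- 1 + (program$amplitude - 1) *
    log_bump(time_h, program$peak_time_h, program$width)
  if (!is.null(program$peak2_time_h)) {
    f <- f + (program$peak2_amplitude - 1) *
      log_bump(time_h, program$peak2_time_h, program$width)
  }
  f
}

program_silenced <- function(program, genotype) {
  if (genotype == "sham") return(TRUE)
  if (genotype %in% c("TLR4ko", "MyD88ko")) {
    return(program$program_class == "inflammatory" &&
             program$compartment == "CP")
  }
  FALSE
}

# does a spot with fine structure label `fine` belong to the program's
# compartment? (lesion tissue is striatal, CP_* collapse to CP)
program_hits <- function(program, fine) {
  fine == program$compartment |
    (!is.na(coarse_region(fine)) & coarse_region(fine) == program$compartment)
}

#' Default temporal programs
#'
#' The planted spatiotemporal structure: an erythrocyte-transcript pulse
#' at 2 h in the blood-exposed compartments (lesion, striatum, choroid
#' plexus), an acute inflammatory choroid-plexus wave peaking at 12 h, a
#' TLR/MyD88-signaling bump in the CP peaking at 24 h, a biphasic Ptprc
#' (CD45) course in the CP (24 h and 96 h), an early striatal cytokine
#' wave (12 h), a delayed phagocytic program building at 48 h, and the
#' late perilesional macrophage wave peaking at 96 h.
#'
#' @return named list of [temporal_program()] objects.
#' @export
default_programs <- function() {
  p <- list(
    temporal_program("ery_STR", c("Hba-a1", "Hba-a2", "Hbb-bs", "Hbb-bt",
                                  "Alas2"),
                     "STR", 2, 6, width = 0.6, class = "blood"),
    temporal_program("ery_CP", c("Hba-a1", "Hba-a2", "Hbb-bs", "Hbb-bt",
                                 "Alas2"),
                     "CP", 2, 6, width = 0.6, class = "blood"),
    temporal_program("ery_lesion", c("Hba-a1", "Hba-a2", "Hbb-bs",
                                     "Hbb-bt", "Alas2"),
                     "lesion", 2, 10, width = 0.6, class = "blood"),
    temporal_program("cp_wave", c("Icam1", "Ccl20", "Cxcl10", "Ccl5",
                                  "Irf7", "Ifi27l2a", "Vcam1", "Bst2",
                                  "Serpina3n", "Lcn2"),
                     "CP", 12, 4),
    temporal_program("cp_tlr", c("Tlr2", "Tlr4", "Myd88", "Irak4",
                                 "Traf6", "Cd14"),
                     "CP", 24, 3, width = 0.4),
    temporal_program("cp_ptprc", "Ptprc", "CP", 24, 3, width = 0.35,
                     peak2_time_h = 96, peak2_amplitude = 2.5),
    temporal_program("str_early", c("Timp1", "Il1b", "Ccl2", "Ccl12",
                                    "Socs3", "Ifit1"),
                     "STR", 12, 4),
    temporal_program("str_mid", c("Trem2", "Tyrobp", "Ctss", "Itgam",
                                  "Cd52", "Fcgr3"),
                     "STR", 48, 3),
    temporal_program("str_late", c("Cd68", "Lyz2", "Hmox1", "Ftl1",
                                   "Mpeg1", "C1qa"),
                     "STR", 96, 4)
  )
  setNames(p, vapply(p, `[[`, character(1), "name"))
}

#' Cohort design
#'
#' Describes the animals of a synthetic experiment: which time points
#' (0 = uninjected control), how many animals per time point, and which
#' genotypes. Expanded to one row per animal.
#'
#' @param time_points_h numeric hours; 0 denotes the uninjected control.
#' @param animals_per_timepoint integer.
#' @param genotypes subset of wildtype, TLR4ko, MyD88ko, sham.
#' @param seed master seed for everything generated from this design.
#' @return object of class `cohort_design` with an `animals` table.
#' @export
cohort_design <- function(time_points_h, animals_per_timepoint = 1L,
                          genotypes = "wildtype", seed = 1L) {
  stopifnot(length(time_points_h) >= 1, animals_per_timepoint >= 1,
            all(genotypes %in% c("wildtype", "TLR4ko", "MyD88ko", "sham")))
  grid <- expand.grid(rep = seq_len(animals_per_timepoint),
                      time_h = time_points_h, genotype = genotypes,
                      stringsAsFactors = FALSE)
  grid$animal <- sprintf("%s_t%03d_a%d", substr(grid$genotype, 1, 4),
                         grid$time_h, grid$rep)
  grid$sample_id <- grid$animal
  structure(
    list(time_points_h = time_points_h,
         animals_per_timepoint = as.integer(animals_per_timepoint),
         genotypes = genotypes, seed = as.integer(seed),
         animals = grid[, c("sample_id", "animal", "time_h", "genotype")]),
    class = "cohort_design"
  )
}

#' @rdname cohort_design
#' @details `default_spot_design()` mirrors the transcriptomics cohort:
#'   one wildtype animal per time point at 0 (control), 2, 12, 24, 48
#'   and 96 h (six samples). `default_histology_design()` uses three
#'   animals per time point at 2, 12, 24, 36, 48 and 96 h.
#'   `default_knockout_design()` is the 24 h genotype series (6
#'   wildtype, 4 per knockout, 4 sham).
#' @export
default_spot_design <- function(seed = 1L) {
  cohort_design(c(0, 2, 12, 24, 48, 96), 1L, "wildtype", seed)
}

#' @rdname cohort_design
#' @export
default_histology_design <- function(seed = 1L,
                                     animals_per_timepoint = 3L) {
  cohort_design(c(2, 12, 24, 36, 48, 96), animals_per_timepoint,
                "wildtype", seed)
}

#' @rdname cohort_design
#' @export
default_knockout_design <- function(seed = 1L) {
  d_wt <- cohort_design(24, 6L, "wildtype", seed)
  d_ko <- cohort_design(24, 4L, c("TLR4ko", "MyD88ko", "sham"), seed)
  animals <- rbind(d_wt$animals, d_ko$animals)
  structure(
    list(time_points_h = 24, animals_per_timepoint = NA_integer_,
         genotypes = c("wildtype", "TLR4ko", "MyD88ko", "sham"),
         seed = as.integer(seed), animals = animals),
    class = "cohort_design"
  )
}

#' Baseline expression table with anatomical markers
#'
#' Per-gene relative baseline expression plus the anatomical-marker
#' assignment: six marker genes for each of the eight scored regions
#' (CTX, STR, TH, CP and the deep-brain constituents PAL, HY, MB, P),
#' boosted `marker_fold`-fold in spots of their region (deep-brain
#' spots express all four deep constituent sets at `deep_fold`).
#' Program genes and background genes complete the universe.
#'
#' @param n_background number of unstructured background genes.
#' @param marker_fold fold-change of a marker in its own region.
#' @param deep_fold fold of PAL/HY/MB/P markers in DEEP spots.
#' @param seed seed for baseline abundances.
#' @return data.frame with columns gene, base_expr, marker_region.
#' @export
default_baseline <- function(n_background = 212L, marker_fold = 8,
                             deep_fold = 5, seed = 42L) {
  markers <- list(
    CTX = c("Slc17a7", "Satb2", "Cux2", "Rorb", "Tbr1", "Mef2c"),
    STR = c("Ppp1r1b", "Drd1", "Drd2", "Adora2a", "Pde10a", "Gpr88"),
    TH = c("Tcf7l2", "Prkcd", "Ntng1", "Ramp3", "Rora", "Slc17a6"),
    CP = c("Ttr", "Folr1", "Clic6", "Kcnj13", "Otx2", "Prlr"),
    PAL = c("Nkx2-1", "Lhx8", "Gbx1", "Isl1", "Zic1", "Magel2"),
    HY = c("Hcrt", "Pmch", "Agrp", "Pomc", "Gal", "Oxt"),
    MB = c("Slc6a3", "Ddc", "Pitx3", "En1", "Foxa2", "Lmx1b"),
    P = c("Phox2b", "Slc6a2", "Dbh", "Tph2", "Fev", "Pou4f1")
  )
  prog_genes <- unique(unlist(lapply(default_programs(), `[[`, "genes")))
  bg <- sprintf("Gene%04d", seq_len(n_background))
  genes <- c(unlist(markers, use.names = FALSE), prog_genes, bg)
  stopifnot(!anyDuplicated(genes))
  region <- c(rep(names(markers), each = 6),
              rep(NA_character_, length(prog_genes) + n_background))
  base <- with_seed(seed, rlnorm(length(genes), meanlog = 0, sdlog = 1))
  df <- data.frame(gene = genes, base_expr = base, marker_region = region,
                   stringsAsFactors = FALSE)
  attr(df, "marker_fold") <- marker_fold
  attr(df, "deep_fold") <- deep_fold
  df
}

#' Anatomical marker gene sets
#'
#' The eight marker sets of [default_baseline()] as a gene-set catalog
#' for anatomical scoring, plus a MyD88-dependent TLR-signaling set used
#' for the pathway score time course.
#'
#' @param baseline a [default_baseline()] table.
#' @return a [gene_set_catalog()].
#' @export
default_marker_sets <- function(baseline = default_baseline()) {
  mk <- baseline[!is.na(baseline$marker_region), ]
  sets <- split(mk$gene, mk$marker_region)
  sets <- sets[intersect(anatomical_regions(), names(sets))]
  sets$MYD88_TLR_SIGNALING <- c("Tlr2", "Tlr4", "Myd88", "Irak4",
                                "Traf6", "Cd14")
  gene_set_catalog(sets, universe = baseline$gene,
                   provenance = "synthetic anatomical markers")
}
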