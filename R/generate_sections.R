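known_channels <- function() {
  c("dextran10", "dextran70", "dextran155", "CD45", "ICAM1", "F480",
    "Hoechst")
}

# biphasic blood-brain-barrier leakage curve (unit peaks at 12 h and a
# larger inflammation-driven peak at 48 h); max value 1.3
leakage_curve <- function(time_h) {
  log_bump(time_h, 12, 0.35) + 1.3 * log_bump(time_h, 48, 0.35)
}

blooded <- function(genotype) genotype %in% c("wildtype", "TLR4ko",
                                              "MyD88ko")
cp_inflammation_on <- function(genotype) genotype == "wildtype"

# mean signal (above tissue base) of a channel in one compartment at
# one time for one genotype; the planted intensity model
channel_signal <- function(channel, compartment, time_h, genotype) {
  is_cp <- compartment %in% c("CP_ipsi", "CP_contra", "CP_third")
  is_peri <- compartment %in% c("STR_ipsi", "lesion")
  s <- 0
  if (startsWith(channel, "dextran")) {
    if (is_cp) {
      amp <- c(CP_ipsi = 3000, CP_third = 2000, CP_contra = 1000)
      s <- s + 800 + amp[[compartment]] * log_bump(time_h, 2, 0.6)
    }
  } else if (channel == "CD45") {
    if (is_cp && blooded(genotype))
      s <- s + 4000 * log_bump(time_h, 24, 0.4)
    if (is_peri && blooded(genotype))
      s <- s + 3000 * log_bump(time_h, 96, 0.4)
  } else if (channel == "ICAM1") {
    if (is_cp && cp_inflammation_on(genotype))
      s <- s + 4000 * log_bump(time_h, 36, 0.4)
    if (is_peri && blooded(genotype))
      s <- s + 800 * log_bump(time_h, 48, 0.4)
  } else if (channel == "F480") {
    if (is_cp) s <- s + 400  # resident epiplexus macrophages
    if (is_cp && cp_inflammation_on(genotype))
      s <- s + 3500 * log_bump(time_h, 24, 0.4)
    if (is_peri && blooded(genotype))
      s <- s + 3000 * log_bump(time_h, 96, 0.4)
  } else if (channel == "Hoechst") {
    s <- s + 2800
  }
  s
}

channel_base <- function(channel) {
  if (startsWith(channel, "dextran")) 300
  else if (channel == "Hoechst") 200
  else 250
}

#' Render one synthetic multichannel section
#'
#' Warps the layout's label image by a planted pose transform (nearest
#' neighbor), assigns each channel its compartment-specific mean signal
#' at the section's time point and genotype, renders the perilesional
#' dextran leakage blob (a plateau disc at the lesion centroid whose
#' radius and intensity follow the biphasic leakage curve), and adds
#' Poisson shot noise on the signal plus Gaussian read noise on top of
#' a constant background offset.
#'
#' @param layout a [section_layout()].
#' @param transform `similarity_transform` mapping template coordinates
#'   to this section's coordinates (the planted pose jitter).
#' @param channels channel names, subset of dextran10/dextran70/
#'   dextran155/CD45/ICAM1/F480/Hoechst.
#' @param time_h,genotype,animal,section_position_um metadata.
#' @param seed RNG seed for the noise.
#' @param background,read_sd background offset and Gaussian read noise
#'   SD (16-bit intensity units).
#' @return a [section_image()] with planted truth attached.
#' @export
render_section <- function(layout, transform, channels, time_h,
                           genotype, animal = "a1",
                           section_position_um = 300, seed = 1L,
                           background = 150, read_sd = 30) {
  bad <- setdiff(channels, known_channels())
  if (length(bad) > 0)
    stop("unknown channel name(s): ", paste(bad, collapse = ", "))
  tmpl <- layout_label_image(layout)
  shape <- c(layout$height_px, layout$width_px)
  labs <- warp_to_template(tmpl$labels, transform, shape, "nearest")
  labs[is.na(labs)] <- 0
  labs <- matrix(as.integer(labs), shape[1], shape[2])
  hemi <- warp_to_template(tmpl$hemispheres, transform, shape, "nearest")
  hemi[is.na(hemi)] <- 0
  hemi <- matrix(as.integer(hemi), shape[1], shape[2])

  lesion_lab <- tmpl$table$label[tmpl$table$compartment == "lesion"]
  lesion_ctr_t <- colMeans(which(tmpl$labels == lesion_lab,
                                 arr.ind = TRUE))
  blob_ctr <- as.numeric(apply_transform(transform,
                                         matrix(lesion_ctr_t, 1)))
  lk <- leakage_curve(time_h)
  # radius capped so the blob never reaches the (dextran-bright)
  # ipsilateral choroid plexus, which would merge components
  blob_r <- (7 + 10 * lk / 1.3) * transform$scale
  blob_i <- 1500 + 4500 * lk / 1.3

  tissue <- labs > 0
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  ccol <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  blob <- tissue &
    (rr - blob_ctr[1])^2 + (ccol - blob_ctr[2])^2 <= blob_r^2

  imgs <- list()
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    mu <- matrix(0, shape[1], shape[2])
    mu[tissue] <- channel_base(ch)
    for (i in seq_len(nrow(tmpl$table))) {
      cmp <- tmpl$table$compartment[i]
      s <- channel_signal(ch, cmp, time_h, genotype)
      if (s > 0) mu[labs == tmpl$table$label[i]] <- mu[labs ==
                                                tmpl$table$label[i]] + s
    }
    if (startsWith(ch, "dextran") && blooded(genotype))
      mu[blob] <- mu[blob] + blob_i
    imgs[[ch]] <- with_seed(child_seed(seed, ci), {
      n <- length(mu)
      img <- background + rpois(n, as.vector(mu)) + rnorm(n, 0, read_sd)
      matrix(pmax(0, img), shape[1], shape[2])
    })
  }

  section_image(
    channels = imgs, mask = labs, label_table = tmpl$table,
    hemispheres = hemi, px_size_um = layout$px_size_um,
    section_position_um = section_position_um, animal = animal,
    time_h = time_h, genotype = genotype,
    truth = list(transform = transform, blob_center = blob_ctr,
                 blob_radius_px = blob_r, blob_intensity = blob_i,
                 leakage_curve = lk)
  )
}

#' Generate a synthetic section-image cohort
#'
#' For every animal of the design: draws a per-animal pose jitter
#' (rotation, translation, scale), lays out a stack of `n_stack`
#' sections at `stack_step_um` spacing starting at a random position
#' shortly before `start_um`, applies the standardized section
#' selection (every `step_sections`-th section from the first at or
#' beyond `start_um`, `n_sections` in total) and renders only the
#' selected sections, each with a small additional per-section jitter.
#'
#' @param layout a [section_layout()].
#' @param design a [cohort_design()].
#' @param channels channels to render (see [render_section()]).
#' @param n_stack,stack_step_um stack geometry (16 sections, 60 um).
#' @param start_um,step_sections,n_sections standardized selection rule
#'   (300 um, every 2nd, 8 sections).
#' @param max_rot_deg,max_shift_px,scale_range per-animal jitter ranges.
#' @return list of [section_image()]s.
#' @export
generate_section_cohort <- function(layout, design,
                                    channels = c("dextran70", "CD45",
                                                 "ICAM1"),
                                    n_stack = 16L, stack_step_um = 60,
                                    start_um = 300, step_sections = 2L,
                                    n_sections = 8L,
                                    max_rot_deg = 10, max_shift_px = 8,
                                    scale_range = c(0.95, 1.05)) {
  bad <- setdiff(channels, known_channels())
  if (length(bad) > 0)
    stop("unknown channel name(s): ", paste(bad, collapse = ", "))
  animals <- design$animals
  out <- list()
  for (i in seq_len(nrow(animals))) {
    an <- animals[i, ]
    aseed <- child_seed(design$seed, 5000L + i)
    jit <- with_seed(aseed, list(
      rot = runif(1, -max_rot_deg, max_rot_deg),
      shift = runif(2, -max_shift_px, max_shift_px),
      scale = runif(1, scale_range[1], scale_range[2]),
      pos0 = runif(1, start_um - stack_step_um + 1, start_um)
    ))
    t_animal <- similarity_transform(jit$rot, jit$scale, jit$shift)
    positions <- jit$pos0 + (seq_len(n_stack) - 1L) * stack_step_um
    sel <- select_standard_sections(positions, start_um, step_sections,
                                    n_sections)
    for (j in seq_along(sel)) {
      sseed <- child_seed(aseed, j)
      sj <- with_seed(sseed, list(
        rot = runif(1, -2, 2), shift = runif(2, -2, 2),
        scale = runif(1, 0.99, 1.01)))
      t_total <- compose_transforms(
        similarity_transform(sj$rot, sj$scale, sj$shift), t_animal)
      out[[length(out) + 1L]] <- render_section(
        layout, t_total, channels, an$time_h, an$genotype,
        animal = an$animal, section_position_um = positions[sel[j]],
        seed = child_seed(sseed, 99L))
    }
  }
  out
}
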