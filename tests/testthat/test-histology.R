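test_that("the standardized section selection follows the printed rule", {
  # 16 consecutive 60-um sections from 300 um: every 2nd, 8 sections
  positions <- 300 + (0:15) * 60
  idx <- select_standard_sections(positions, 300, 2L, 8L)
  expect_equal(idx, seq(1L, 15L, by = 2L))
  expect_length(idx, 8L)

  expect_equal(select_standard_sections(positions, 300, 2L, 1L), 1L)
  # a 10-section stack cannot supply 8 every-second sections (needs 15)
  expect_error(select_standard_sections(positions[1:10], 300, 2L, 8L),
               "short by 5")
  expect_error(select_standard_sections(positions, 2000, 2L, 1L),
               "no section at or beyond")
  expect_error(select_standard_sections(rev(positions), 300, 2L, 8L),
               "sorted")
})

test_that("similarity transforms compose and invert exactly", {
  a <- similarity_transform(23, 1.1, c(4, -7))
  b <- similarity_transform(-11, 0.9, c(-2, 3))
  pts <- matrix(rnorm(20, sd = 50), ncol = 2)
  expect_equal(apply_transform(compose_transforms(a, b), pts),
               apply_transform(a, apply_transform(b, pts)),
               tolerance = 1e-10)
  rt <- apply_transform(invert_transform(a), apply_transform(a, pts))
  expect_lt(max(abs(rt - pts)), 1e-6)
})

test_that("registration of the template to itself is the identity", {
  tmpl <- layout_label_image(test_layout())
  tr <- estimate_registration(tmpl$labels, tmpl$labels, tmpl$table)
  expect_lt(abs(tr$rotation_deg), 1e-3)
  expect_lt(abs(tr$scale - 1), 1e-6)
  expect_lt(max(abs(tr$translation)), 1e-3)
  expect_lt(attr(tr, "residual"), 0.5)
})

test_that("planted poses are recovered within tolerance", {
  lay <- test_layout()
  tmpl <- layout_label_image(lay)
  for (planted in list(similarity_transform(10, 1, c(5, -3)),
                       similarity_transform(-6, 1.1, c(2, 8)))) {
    warped <- warp_to_template(tmpl$labels, planted, dim(tmpl$labels),
                               "nearest")
    warped[is.na(warped)] <- 0
    est <- estimate_registration(matrix(as.integer(warped),
                                        nrow(warped)),
                                 tmpl$labels, tmpl$table)
    inv <- invert_transform(planted)
    expect_lt(abs(est$rotation_deg - inv$rotation_deg), 0.5)
    expect_lt(abs(est$scale - inv$scale) / inv$scale, 0.01)
    expect_lt(max(abs(est$translation - inv$translation)), 0.5)
  }
  expect_error(estimate_registration(matrix(0L, 4, 4), tmpl$labels,
                                     tmpl$table),
               "outline missing")
})

test_that("warping preserves identity, constants and round trips", {
  set.seed(8)
  img <- matrix(rnorm(64 * 64), 64, 64)
  idt <- warp_to_template(img, similarity_transform(), dim(img))
  expect_equal(idt[2:63, 2:63], img[2:63, 2:63], tolerance = 1e-12)

  tr <- similarity_transform(15, 1.05, c(3, -2))
  const <- warp_to_template(matrix(7, 64, 64), tr, c(64, 64))
  expect_lt(max(abs(const[!is.na(const)] - 7)), 1e-9)

  # smooth image: warp then inverse-warp within 1% of dynamic range
  smooth <- outer(seq(0, 1, length.out = 128),
                  seq(0, 2, length.out = 128), function(a, b)
                    sin(4 * a) + cos(3 * b))
  fwd <- warp_to_template(smooth, tr, c(128, 128))
  fwd_filled <- fwd; fwd_filled[is.na(fwd)] <- 0
  back <- warp_to_template(fwd_filled, invert_transform(tr),
                           c(128, 128))
  core <- 20:108
  err <- abs(back[core, core] - smooth[core, core])
  expect_lt(mean(err, na.rm = TRUE), 0.01 * diff(range(smooth)))
})

test_that("average maps reduce to the single-section and linear cases", {
  lay <- test_layout()
  tmpl <- layout_label_image(lay)
  sec <- render_section(lay, similarity_transform(2, 1, c(1, -1)),
                        "Hoechst", 24, "wildtype", seed = 3)
  m1 <- average_intensity_map(list(sec), "Hoechst", tmpl$labels,
                              tmpl$table)
  tr <- estimate_registration(sec$mask, tmpl$labels, sec$label_table,
                              tmpl$table)
  direct <- warp_to_template(normalize_section(sec, "Hoechst"), tr,
                             dim(tmpl$labels))
  expect_equal(m1$map, direct, tolerance = 1e-12)

  # two constant sections 10 and 20 (normalizer off): map constant 15
  mk_const <- function(v) {
    s <- sec
    s$channels$Hoechst <- matrix(v, nrow(sec$mask), ncol(sec$mask))
    s
  }
  m2 <- average_intensity_map(list(mk_const(10), mk_const(20)),
                              "Hoechst", tmpl$labels, tmpl$table,
                              normalize = FALSE)
  vals <- m2$map[m2$coverage == 2L]
  expect_true(all(abs(vals - 15) < 1e-9))

  # linearity on shared coverage
  ma <- average_intensity_map(list(mk_const(4)), "Hoechst",
                              tmpl$labels, tmpl$table,
                              normalize = FALSE)
  mb <- average_intensity_map(list(mk_const(10)), "Hoechst",
                              tmpl$labels, tmpl$table,
                              normalize = FALSE)
  mab <- average_intensity_map(list(mk_const(2 * 4 + 3 * 10)),
                               "Hoechst", tmpl$labels, tmpl$table,
                               normalize = FALSE)
  on_cov <- !is.na(ma$map)
  expect_equal(mab$map[on_cov], 2 * ma$map[on_cov] + 3 * mb$map[on_cov],
               tolerance = 1e-9)
})

test_that("connected-component labeling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[cbind(c(2, 3, 5), c(2, 3, 5))] <- TRUE  # two diagonal groups
  lab <- cpwave:::label_components(m)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(lab[5, 5] != lab[2, 2])
  expect_equal(max(lab), 2L)
})

test_that("leakage quantification matches the analytic disc", {
  set.seed(12)
  nr <- 200
  img <- matrix(rnorm(nr * nr, 10, 2), nr, nr)
  rr <- row(img); cc <- col(img)
  disc <- (rr - 100)^2 + (cc - 100)^2 <= 25^2
  img[disc] <- 100
  bg <- rr < 30
  res <- quantify_leakage(img, c(100, 100), bg, k_sigma = 3,
                          px_size_um = 20)
  expect_lt(abs(res$area_mm2 - pi * 25^2 * 0.02^2) /
              (pi * 25^2 * 0.02^2), 0.05)
  expect_equal(res$mean_intensity, 100, tolerance = 2)

  # uniform image: no leakage, intensity missing
  uni <- matrix(rnorm(100 * 100, 10, 1), 100, 100)
  res0 <- quantify_leakage(uni, c(50, 50), matrix(TRUE, 100, 100) &
                             row(uni) < 20, 3, 20)
  expect_equal(res0$area_mm2, 0)
  expect_true(is.na(res0$mean_intensity))

  # of two discs, only the one within 200 um of the site counts
  img2 <- matrix(rnorm(nr * nr, 10, 2), nr, nr)
  near <- (rr - 100)^2 + (cc - 100)^2 <= 8^2
  far <- (rr - 100)^2 + (cc - 170)^2 <= 20^2
  img2[near | far] <- 100
  res2 <- quantify_leakage(img2, c(100, 100), rr < 30, 3, 20)
  expect_lt(abs(res2$area_mm2 - sum(near) * 0.02^2), 0.02)
})

test_that("leakage area is non-increasing in k_sigma", {
  set.seed(13)
  img <- matrix(rnorm(150 * 150, 10, 3), 150, 150)
  disc <- (row(img) - 75)^2 + (col(img) - 75)^2 <= 20^2
  img[disc] <- img[disc] + 30
  bg <- row(img) < 25
  areas <- vapply(c(1, 2, 3, 4, 6), function(k) {
    quantify_leakage(img, c(75, 75), bg, k, 20)$area_mm2
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-12))
})

test_that("compartment means handle constants, checkerboards and orderings", {
  lay <- test_layout()
  sec <- render_section(lay, similarity_transform(), "dextran70", 2,
                        "wildtype", seed = 30)
  const <- sec
  const$channels$dextran70 <- matrix(42, nrow(sec$mask), ncol(sec$mask))
  cm <- compartment_mean_intensity(const, "dextran70",
                                   c("CP_ipsi", "TH"),
                                   normalize = FALSE)
  expect_equal(unname(cm), c(42, 42))

  board <- sec
  chk <- matrix(0, nrow(sec$mask), ncol(sec$mask))
  chk[(row(chk) + col(chk)) %% 2 == 0] <- 100
  board$channels$dextran70 <- chk
  cm2 <- compartment_mean_intensity(board, "dextran70", "TH",
                                    normalize = FALSE)
  expect_equal(unname(cm2), 50, tolerance = 1)

  # dextran at 2 h: CP_ipsi > CP_third > CP_contra
  cm3 <- compartment_mean_intensity(sec, "dextran70",
                                    c("CP_ipsi", "CP_third",
                                      "CP_contra"))
  expect_true(cm3[["CP_ipsi"]] > cm3[["CP_third"]])
  expect_true(cm3[["CP_third"]] > cm3[["CP_contra"]])

  expect_message(
    out <- compartment_mean_intensity(sec, "dextran70", "nonexistent"),
    "empty")
  expect_true(is.na(out[["nonexistent"]]))
})
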