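#' Similarity transform (rotation, isotropic scale, translation)
#'
#' Maps a point `p = (row, col)` to `s * R(theta) %*% p + t`. Used both
#' to plant per-animal pose jitter in the synthetic section generator
#' and to register sections to the template.
#'
#' @param rotation_deg rotation angle in degrees (counter-clockwise in
#'   row/col coordinates).
#' @param scale isotropic scale, > 0.
#' @param translation numeric length-2 `(row, col)` offset in pixels.
#' @return object of class `similarity_transform`.
#' @export
similarity_transform <- function(rotation_deg = 0, scale = 1,
                                 translation = c(0, 0)) {
  stopifnot(scale > 0, length(translation) == 2)
  structure(list(rotation_deg = rotation_deg, scale = scale,
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity_transform: rot %.3f deg, scale %.4f, shift (%.3f, %.3f)\n",
              x$rotation_deg, x$scale, x$translation[1], x$translation[2]))
  invisible(x)
}

rot_mat <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Apply, compose and invert similarity transforms
#'
#' `apply_transform` maps an n x 2 matrix of (row, col) points;
#' `compose_transforms(a, b)` returns the transform "b then a";
#' `invert_transform` the exact inverse (round trip is identity to
#' numerical precision).
#'
#' @param transform,a,b `similarity_transform` objects.
#' @param points n x 2 numeric matrix of (row, col) coordinates.
#' @return transformed points / a `similarity_transform`.
#' @export
apply_transform <- function(transform, points) {
  points <- matrix(points, ncol = 2)
  t(transform$scale * rot_mat(transform$rotation_deg) %*% t(points) +
      transform$translation)
}

#' @rdname apply_transform
#' @export
compose_transforms <- function(a, b) {
  # x -> a(b(x)): s_a R_a (s_b R_b x + t_b) + t_a
  similarity_transform(
    rotation_deg = a$rotation_deg + b$rotation_deg,
    scale = a$scale * b$scale,
    translation = as.numeric(a$scale * rot_mat(a$rotation_deg) %*%
                               b$translation + a$translation)
  )
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  s <- 1 / transform$scale
  r <- -transform$rotation_deg
  similarity_transform(
    rotation_deg = r, scale = s,
    translation = as.numeric(-s * rot_mat(r) %*% transform$translation)
  )
}

mask_moments <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  ctr <- colMeans(idx)
  d <- sweep(idx, 2, ctr)
  mu20 <- mean(d[, 1]^2); mu02 <- mean(d[, 2]^2)
  mu11 <- mean(d[, 1] * d[, 2])
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  list(centroid = ctr, area = n, theta_deg = theta * 180 / pi)
}

#' Estimate section-to-template registration from masks
#'
#' Moments-based similarity registration of a section's outline to the
#' template outline: the translation aligns the centroids, the rotation
#' the principal axes, the scale the square root of the area ratio.
#' The 180-degree ambiguity of the principal axis is resolved by the
#' side on which the ipsilateral ventricle/choroid-plexus centroid
#' lands. The residual (mean distance from warped section boundary
#' points to the nearest template boundary point, in template pixels)
#' is reported; above `residual_threshold` the fit is flagged
#' low-confidence.
#'
#' @param mask section label image (integer matrix, 0 = background).
#' @param template_mask template label image of the same layout.
#' @param table,template_table label tables (label, compartment,
#'   hemisphere) for the two mask images.
#' @param residual_threshold low-confidence threshold in pixels.
#' @return a `similarity_transform` (section -> template) with
#'   attributes `residual` and `low_confidence`.
#' @export
estimate_registration <- function(mask, template_mask, table,
                                  template_table = table,
                                  residual_threshold = 3) {
  if (!any(mask > 0) || !any(template_mask > 0))
    stop("section outline missing (empty mask)")
  ms <- mask_moments(mask > 0)
  mt <- mask_moments(template_mask > 0)
  scale <- sqrt(mt$area / ms$area)
  rot <- (mt$theta_deg - ms$theta_deg) %% 180
  if (rot >= 90) rot <- rot - 180

  ipsi_centroid <- function(m, tab) {
    labs <- tab$label[tab$hemisphere == "ipsi"]
    sel <- m %in% labs
    if (!any(sel)) stop("no ipsilateral structure label in mask")
    colMeans(which(matrix(sel, nrow(m)), arr.ind = TRUE))
  }
  ci_s <- ipsi_centroid(mask, table)
  ci_t <- ipsi_centroid(template_mask, template_table)

  best <- NULL
  for (r in c(rot, rot + 180)) {
    tr <- similarity_transform(
      rotation_deg = r, scale = scale,
      translation = as.numeric(mt$centroid - scale * rot_mat(r) %*%
                                 ms$centroid))
    d <- sum((apply_transform(tr, matrix(ci_s, 1)) - ci_t)^2)
    if (is.null(best) || d < best$d) best <- list(tr = tr, d = d)
  }
  tr <- best$tr

  bs <- boundary_points(mask > 0, 400)
  bt <- boundary_points(template_mask > 0, 800)
  wb <- apply_transform(tr, bs)
  d2 <- outer(rowSums(wb^2), rowSums(bt^2), "+") - 2 * tcrossprod(wb, bt)
  residual <- mean(sqrt(pmax(0, apply(d2, 1, min))))
  attr(tr, "residual") <- residual
  attr(tr, "low_confidence") <- residual > residual_threshold
  if (residual > residual_threshold)
    cpw_warn("registration residual ", signif(residual, 3),
             " px exceeds ", residual_threshold, " px; low confidence")
  tr
}

# subsampled outer-boundary pixel coordinates of a binary mask
boundary_points <- function(mask, max_points = 400) {
  nr <- nrow(mask); nc <- ncol(mask)
  inner <- mask
  inner[2:(nr - 1), 2:(nc - 1)] <-
    mask[2:(nr - 1), 2:(nc - 1)] & mask[1:(nr - 2), 2:(nc - 1)] &
    mask[3:nr, 2:(nc - 1)] & mask[2:(nr - 1), 1:(nc - 2)] &
    mask[2:(nr - 1), 3:nc]
  pts <- which(mask & !inner, arr.ind = TRUE)
  if (nrow(pts) > max_points)
    pts <- pts[round(seq(1, nrow(pts), length.out = max_points)), ]
  pts
}

#' Warp an image into template space
#'
#' Inverse-maps every template pixel through the transform and
#' interpolates the source image: bilinear for intensities, nearest
#' neighbor for label images. Pixels that fall outside the source
#' field of view are `NA` (missing, never zero-filled), so they drop
#' out of downstream averaging.
#'
#' @param image numeric (or integer label) matrix.
#' @param transform a `similarity_transform` mapping source (section)
#'   coordinates to template coordinates.
#' @param template_shape integer `c(rows, cols)` of the output.
#' @param interp `"bilinear"` or `"nearest"`.
#' @return matrix of size `template_shape` with `NA` outside coverage.
#' @export
warp_to_template <- function(image, transform,
                             template_shape = dim(image),
                             interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  nr <- template_shape[1]; nc <- template_shape[2]
  inv <- invert_transform(transform)
  pts <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  src <- apply_transform(inv, pts)
  r <- src[, 1]; c <- src[, 2]
  sr <- nrow(image); sc <- ncol(image)
  out <- rep(NA_real_, nr * nc)

  if (interp == "nearest") {
    ri <- round(r); ci <- round(c)
    ok <- ri >= 1 & ri <= sr & ci >= 1 & ci <= sc
    out[ok] <- image[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(r); c0 <- floor(c)
    ok <- r0 >= 1 & r0 + 1 <= sr & c0 >= 1 & c0 + 1 <= sc
    fr <- r[ok] - r0[ok]; fc <- c[ok] - c0[ok]
    i00 <- image[cbind(r0[ok], c0[ok])]
    i10 <- image[cbind(r0[ok] + 1, c0[ok])]
    i01 <- image[cbind(r0[ok], c0[ok] + 1)]
    i11 <- image[cbind(r0[ok] + 1, c0[ok] + 1)]
    out[ok] <- i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
      i01 * (1 - fr) * fc + i11 * fr * fc
  }
  matrix(out, nr, nc)
}
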