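# Contour extraction, orientation estimation and intensity sampling.
#
# Contour pixels live on the shading-gradient side of the mask boundary
# (non-mask pixels with at least one 8-neighbor in the mask), so
# intensity sampled at inset 1 never reads mask gray.  Orientation is
# estimated in two stages: an undirected tangent from local PCA of
# contour coordinates in a centered window, then a 360-degree
# into-mask normal obtained by probing 2 px along both tangent
# perpendiculars and keeping the one that lands in the mask.  All
# positions are 1-based (x = column, y = row, origin top-left); angles
# use the display convention (90 deg = up on screen).

#' Extract contour pixel positions from a level-cut mask
#'
#' Returns the gradient-side boundary: non-mask pixels that have at
#' least one mask pixel in their 8-neighborhood.
#'
#' @param m a `level_cut_mask` containing both mask and non-mask pixels.
#' @return Data frame with columns `x` (column) and `y` (row), 1-based.
#' @export
extract_contour_pixels <- function(m) {
  stopifnot(inherits(m, "level_cut_mask"))
  msk <- m$mask
  if (all(msk) || !any(msk)) stop_invalid("mask is uniform: no contour exists")
  n <- nrow(msk); mm <- ncol(msk)
  # dilate mask by one pixel (8-connected) via shifted copies
  pad <- matrix(FALSE, n + 2, mm + 2)
  pad[2:(n + 1), 2:(mm + 1)] <- msk
  dil <- matrix(FALSE, n, mm)
  for (dr in -1:1) for (dc in -1:1) {
    dil <- dil | pad[(2 + dr):(n + 1 + dr), (2 + dc):(mm + 1 + dc)]
  }
  sel <- which(dil & !msk, arr.ind = TRUE)
  data.frame(x = as.integer(sel[, 2]), y = as.integer(sel[, 1]))
}

#' Undirected contour tangent from local PCA
#'
#' For each contour pixel, the principal axis of the contour-pixel
#' coordinates inside a centered `window` x `window` block gives the
#' local tangent as an angle in `[0, 180)` (display convention).
#' Pixels with fewer than 3 contour pixels in their window are flagged
#' invalid.
#'
#' @param positions data frame with `x`, `y` columns (from
#'   [extract_contour_pixels]).
#' @param window odd block side in pixels, at least 3 (default 9).
#' @return Numeric vector of tangent angles in degrees `[0, 180)`, `NA`
#'   where invalid.
#' @export
estimate_orientation_180 <- function(positions, window = 9) {
  if (window < 3 || window %% 2 == 0) stop_invalid("window must be odd and >= 3")
  r <- (window - 1) / 2
  x <- positions$x; y <- positions$y
  npix <- length(x)
  out <- rep(NA_real_, npix)
  for (i in seq_len(npix)) {
    in_win <- which(abs(x - x[i]) <= r & abs(y - y[i]) <= r)
    if (length(in_win) < 3) next
    # display coordinates: u right, v up
    u <- x[in_win]; v <- -y[in_win]
    cu <- u - mean(u); cv <- v - mean(v)
    suu <- sum(cu * cu); svv <- sum(cv * cv); suv <- sum(cu * cv)
    # principal-axis angle of the 2x2 scatter matrix
    ang <- 0.5 * atan2(2 * suv, suu - svv)
    out[i] <- wrap180(rad2deg(ang))
  }
  out
}

#' Disambiguate tangents into 360-degree into-mask normals
#'
#' The two normal candidates are `tangent + 90` and `tangent - 90`
#' degrees.  A probe is taken `probe` px along each candidate from the
#' contour pixel; the candidate whose probe lands inside the mask is the
#' into-mask normal.  If both or neither probe lands in the mask (thin
#' necks, image border) the pixel is flagged invalid.
#'
#' @param m the `level_cut_mask` the contour came from.
#' @param positions contour positions (data frame `x`, `y`).
#' @param tangents tangent angles from [estimate_orientation_180].
#' @param probe probe distance in pixels (default 2).
#' @return Orientations in degrees `[0, 360)`, `NA` where invalid.
#' @export
disambiguate_orientation_360 <- function(m, positions, tangents, probe = 2) {
  stopifnot(inherits(m, "level_cut_mask"))
  msk <- m$mask
  n <- nrow(msk); mm <- ncol(msk)
  in_mask_at <- function(px, py) {
    ok <- !is.na(px) & !is.na(py) & px >= 1 & px <= mm & py >= 1 & py <= n
    res <- rep(FALSE, length(px))
    res[ok] <- msk[cbind(py[ok], px[ok])]
    res
  }
  cand1 <- wrap360(tangents + 90)
  cand2 <- wrap360(tangents - 90)
  probe_hit <- function(ang) {
    px <- as.integer(round(positions$x + probe * cos(deg2rad(ang))))
    py <- as.integer(round(positions$y - probe * sin(deg2rad(ang))))
    in_mask_at(px, py)
  }
  h1 <- probe_hit(cand1)
  h2 <- probe_hit(cand2)
  out <- rep(NA_real_, length(tangents))
  one <- !is.na(tangents) & xor(h1, h2)
  out[one & h1] <- cand1[one & h1]
  out[one & h2] <- cand2[one & h2]
  out
}

#' Sample shading intensity adjacent to the contour
#'
#' Samples the image `inset` pixels along the negated orientation (into
#' the gradient side) with nearest-pixel rounding.  An inset of 0
#' samples the contour pixel itself (used for ribbon stimuli whose
#' luminance lies on the contour path).
#'
#' @param img a [shaded_image].
#' @param positions contour positions (data frame `x`, `y`).
#' @param orientations into-mask orientations in degrees (from
#'   [disambiguate_orientation_360]).
#' @param inset sampling distance in pixels (default 1).
#' @return Intensities in `[0, 1]`, `NA` where the orientation is
#'   invalid or the probe falls off the image.
#' @export
sample_adjacent_intensity <- function(img, positions, orientations, inset = 1) {
  stopifnot(inherits(img, "shaded_image"))
  L <- img$luminance
  n <- nrow(L); mm <- ncol(L)
  px <- as.integer(round(positions$x - inset * cos(deg2rad(orientations))))
  py <- as.integer(round(positions$y + inset * sin(deg2rad(orientations))))
  ok <- !is.na(orientations) & px >= 1 & px <= mm & py >= 1 & py <= n
  out <- rep(NA_real_, nrow(positions))
  out[ok] <- L[cbind(py[ok], px[ok])]
  out
}

#' Full contour measurement of a masked image
#'
#' Convenience wrapper running extraction, tangent estimation, 360
#' degree disambiguation and intensity sampling in one step.
#'
#' @param img a [shaded_image].
#' @param m the `level_cut_mask` composited over it.
#' @param window PCA window for [estimate_orientation_180].
#' @param inset sampling inset for [sample_adjacent_intensity].
#' @return A `contour_pixels` data frame: `x`, `y`, `orientation_deg`,
#'   `intensity`, `valid`.
#' @export
measure_contour <- function(img, m, window = 9, inset = 1) {
  pos <- extract_contour_pixels(m)
  tang <- estimate_orientation_180(pos, window = window)
  ori <- disambiguate_orientation_360(m, pos, tang)
  int <- sample_adjacent_intensity(img, pos, ori, inset = inset)
  out <- data.frame(x = pos$x, y = pos$y, orientation_deg = ori,
                    intensity = int, valid = !is.na(ori) & !is.na(int))
  class(out) <- c("contour_pixels", "data.frame")
  out
}

#' Ground-truth surface tilt map of a height field
#'
#' The image-projected surface normal of a height field points along
#' `-grad h`; its direction in display convention is the surface tilt.
#' Undefined (NA) where the gradient vanishes.
#'
#' @param h a smooth [height_field].
#' @return Matrix of tilt angles in degrees `[0, 360)`, `NA` where flat.
#' @export
ground_truth_tilt <- function(h) {
  surface_orientation_maps(h)$tilt
}
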