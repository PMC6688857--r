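# Lambertian shading of height fields under collimated light.
#
# Observer-centric spherical coordinates: surface orientation is
# (tilt, slant) with tilt the image-plane direction of the projected
# surface normal (degrees, 90 = up on screen) and slant the angle from
# the viewing axis; the light direction is (azimuth, elevation) in the
# same frame.  Under these conventions Lambert's cosine law is the
# spherical law of cosines,
#   L = max(0, r * i * (cos(slant) cos(elev) +
#                       sin(slant) sin(elev) cos(tilt - azimuth))),
# i.e. for fixed light the luminance over pixels of equal slant is an
# exact cosine of tilt with phase equal to the light azimuth.  At a
# self-occluding rim slant -> 90 deg, the offset term vanishes and
#   L = max(0, B cos(theta_rim - C)),
# the rim falloff implemented by rim_luminance().

#' Collimated light source
#'
#' @param azimuth image-plane direction the light comes from, degrees
#'   (90 = from above on screen).
#' @param elevation angle between light and viewing direction, degrees
#'   in `[0, 180]` (0 = head-on from the viewpoint).
#' @param strength dimensionless illumination intensity `i >= 0`.
#' @return A `collimated_light` list.
#' @export
collimated_light <- function(azimuth = 90, elevation = 45, strength = 5) {
  if (strength < 0) stop_invalid("light strength must be non-negative")
  if (elevation < 0 || elevation > 180) {
    stop_invalid("light elevation must be in [0, 180] degrees")
  }
  structure(list(azimuth = wrap360(azimuth), elevation = elevation,
                 strength = strength), class = "collimated_light")
}

#' Lambertian material
#'
#' @param albedo achromatic albedo `r` in `[0, 1]`.
#' @return A `material` list.
#' @export
lambertian_material <- function(albedo = 0.3) {
  if (albedo < 0 || albedo > 1) stop_invalid("albedo must be in [0, 1]")
  structure(list(albedo = albedo), class = "material")
}

# Unit 3D vector from (direction-in-image, angle-from-viewing-axis),
# observer-centric: z toward viewer.
sph_unit <- function(theta_deg, phi_deg) {
  th <- deg2rad(theta_deg); ph <- deg2rad(phi_deg)
  c(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph))
}

#' Lambertian luminance of an oriented patch
#'
#' Lambert's cosine law in observer-centric spherical coordinates,
#' clipped at zero for unilluminated orientations.
#'
#' @param tilt surface tilt, degrees (ignored when `slant == 0`).
#' @param slant surface slant, degrees in `[0, 90]`.
#' @param light a [collimated_light].
#' @param material a [lambertian_material].
#' @return Relative luminance `max(0, r * i * (n . l))` (vectorized over
#'   `tilt`/`slant`).
#' @examples
#' lambert_luminance(90, 45, collimated_light(90, 45, 1),
#'                   lambertian_material(1))  # facing the light: 1
#' @export
lambert_luminance <- function(tilt, slant, light = collimated_light(),
                              material = lambertian_material()) {
  stopifnot(inherits(light, "collimated_light"), inherits(material, "material"))
  if (any(slant < 0 | slant > 90)) stop_invalid("slant must be in [0, 90]")
  ndotl <- cos(deg2rad(slant)) * cos(deg2rad(light$elevation)) +
    sin(deg2rad(slant)) * sin(deg2rad(light$elevation)) *
      cos(deg2rad(tilt - light$azimuth))
  pmax(0, material$albedo * light$strength * ndotl)
}

#' Cosine falloff parameters
#'
#' Parameters of the tilt-cosine luminance law `L = max(0, A + B
#' cos(theta - C))`: at a self-occluding rim the offset `A` is zero and
#' luminance falls off as a pure cosine of rim orientation.
#'
#' @param amplitude cosine amplitude `B >= 0` (luminance units).
#' @param offset vertical offset `A` (luminance units).
#' @param phase phase `C` in degrees; the orientation of maximal
#'   luminance (the light azimuth for a physical rim).
#' @return A `cosine_falloff` list.
#' @export
cosine_falloff <- function(amplitude, offset = 0, phase = 90) {
  if (amplitude < 0) stop_invalid("amplitude must be non-negative")
  structure(list(amplitude = amplitude, offset = offset,
                 phase = wrap360(phase)), class = "cosine_falloff")
}

#' Rim luminance as a cosine of contour orientation
#'
#' Shading adjacent to a self-occluding rim, where slant is 90 degrees:
#' `L = max(0, B cos(theta_rim - C))`.
#'
#' @param theta_rim rim orientation(s), degrees in `[0, 360)`.
#' @param falloff a [cosine_falloff]; its offset is ignored (zero at the
#'   rim limit).
#' @return Relative luminance (vectorized).
#' @export
rim_luminance <- function(theta_rim, falloff) {
  stopifnot(inherits(falloff, "cosine_falloff"))
  pmax(0, falloff$amplitude * cos(deg2rad(theta_rim - falloff$phase)))
}

#' Shaded image container
#'
#' @param luminance numeric matrix of relative luminance in `[0, 1]`.
#' @param bit_depth `"float"`, `8` or `16`; quantization, when
#'   requested, is the last step applied.
#' @param display_scale normalization factor that was applied.
#' @return An object of class `shaded_image`.
#' @export
shaded_image <- function(luminance, bit_depth = "float", display_scale = 1) {
  luminance <- as.matrix(luminance)
  if (any(luminance < -1e-12 | luminance > 1 + 1e-12)) {
    stop_invalid("luminance must lie in [0, 1]")
  }
  structure(list(luminance = pmin(pmax(luminance, 0), 1),
                 bit_depth = bit_depth, display_scale = display_scale),
            class = "shaded_image")
}

#' @export
print.shaded_image <- function(x, ...) {
  cat(sprintf("<shaded_image> %d x %d, range [%.3f, %.3f], depth %s\n",
              nrow(x$luminance), ncol(x$luminance),
              min(x$luminance), max(x$luminance), as.character(x$bit_depth)))
  invisible(x)
}

#' @export
plot.shaded_image <- function(x, ...) {
  graphics::image(t(x$luminance)[, rev(seq_len(nrow(x$luminance)))],
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  axes = FALSE, ...)
  invisible(x)
}

# Surface tilt/slant maps from a height field by central differences.
# Display convention: x right (columns), y up (rows flipped).  Returns
# list(tilt, slant) in degrees; tilt is NA where slant == 0.
surface_orientation_maps <- function(h) {
  stopifnot(inherits(h, "height_field"))
  z <- h$heights
  n <- nrow(z); m <- ncol(z); p <- h$pixel_pitch
  # d/dcol (x, rightward)
  gx <- (z[, c(2:m, m)] - z[, c(1, 1:(m - 1))]) /
    (p * rep(c(1, rep(2, m - 2), 1), each = n))
  # d/drow, then flip sign for display-up
  gr <- (z[c(2:n, n), ] - z[c(1, 1:(n - 1)), ]) /
    (p * rep(c(1, rep(2, n - 2), 1), times = m))
  gy <- -gr
  slant <- rad2deg(atan(sqrt(gx^2 + gy^2)))
  tilt <- wrap360(rad2deg(atan2(-gy, -gx)))   # projected normal = -grad h
  tilt[slant == 0] <- NA_real_
  list(tilt = tilt, slant = slant)
}

#' Render a height field with Lambertian shading
#'
#' Computes per-pixel surface orientation from central differences of
#' the height field (orthographic viewing) and applies Lambert's cosine
#' law under a collimated light.
#'
#' @param h a [height_field].
#' @param light a [collimated_light].
#' @param material a [lambertian_material].
#' @param normalize `"fixed"` (divide by `r * i`, so a fronto-parallel
#'   plane maps to `cos(elevation) < 1`; the default), `"max"` (scale
#'   the maximum to 1), or `"none"`.
#' @param bit_depth `"float"` (default), `8`, or `16`; integer depths
#'   quantize as the final step.
#' @return A [shaded_image]; `display_scale` records the normalization
#'   divisor.
#' @export
render_height_field <- function(h, light = collimated_light(),
                                material = lambertian_material(),
                                normalize = c("fixed", "max", "none"),
                                bit_depth = "float") {
  normalize <- match.arg(normalize)
  o <- surface_orientation_maps(h)
  tilt0 <- ifelse(is.na(o$tilt), 0, o$tilt)   # tilt irrelevant at slant 0
  L <- lambert_luminance(tilt0, o$slant, light, material)
  scale <- switch(normalize,
                  fixed = material$albedo * light$strength,
                  max = max(L),
                  none = 1)
  if (scale <= 0) scale <- 1
  L <- pmin(pmax(L / scale, 0), 1)
  L <- quantize_luminance(L, bit_depth)
  shaded_image(matrix(L, nrow(h$heights), ncol(h$heights)),
               bit_depth = bit_depth, display_scale = scale)
}

quantize_luminance <- function(L, bit_depth) {
  if (identical(bit_depth, "float")) return(L)
  levels <- 2^as.integer(bit_depth) - 1
  round(L * levels) / levels
}

#' Composite a gray level-cut mask over a shaded image
#'
#' Masked pixels are replaced by a homogeneous gray; unmasked pixels are
#' bit-identical to the input.  `gray = "mean"` uses the mean of the
#' input image over all pixels, matching the construction in which the
#' mask luminance is set to the average of the original gradient image.
#'
#' @param img a [shaded_image].
#' @param m a `level_cut_mask` of the same shape.
#' @param gray fill luminance in `[0, 1]`, or `"mean"`.
#' @return A [shaded_image].
#' @export
apply_mask <- function(img, m, gray = "mean") {
  stopifnot(inherits(img, "shaded_image"), inherits(m, "level_cut_mask"))
  if (!all(dim(img$luminance) == dim(m$mask))) {
    stop_invalid("image and mask shapes differ")
  }
  g <- if (identical(gray, "mean")) mean(img$luminance) else {
    if (!is.numeric(gray) || gray < 0 || gray > 1) {
      stop_invalid("gray must be 'mean' or a luminance in [0, 1]")
    }
    gray
  }
  L <- img$luminance
  L[m$mask] <- g
  out <- img
  out$luminance <- L
  out
}
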