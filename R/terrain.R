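# Terrain synthesis and level-cut masks.
#
# Height fields emulate smoothly deformed "terrain" relief: seeded
# Gaussian white noise low-pass filtered isotropically in the frequency
# domain, then amplitude-scaled.  Heights increase toward the viewer;
# the level-cut plane is fronto-parallel, so a cut is a height threshold.

#' Construct a height field object
#'
#' @param heights numeric matrix of relief values; larger = nearer to the
#'   viewer.
#' @param pixel_pitch length units per pixel.
#' @param seed integer seed the field was generated from, or `NA`.
#' @return An object of class `height_field`: a list with elements
#'   `heights`, `pixel_pitch`, `seed`.
#' @export
height_field <- function(heights, pixel_pitch = 1, seed = NA_integer_) {
  heights <- as.matrix(heights)
  if (!all(is.finite(heights))) stop_invalid("heights must be finite everywhere")
  if (pixel_pitch <= 0) stop_invalid("pixel_pitch must be positive")
  structure(list(heights = heights, pixel_pitch = pixel_pitch, seed = seed),
            class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  cat(sprintf("<height_field> %d x %d, relief range [%.4g, %.4g], pitch %g\n",
              nrow(x$heights), ncol(x$heights),
              min(x$heights), max(x$heights), x$pixel_pitch))
  invisible(x)
}

#' Generate a seeded band-limited terrain height field
#'
#' Gaussian white noise is low-pass filtered in the frequency domain
#' with a hard isotropic cutoff, giving a smooth deformed-terrain
#' relief.  The field is exactly zero-mean before amplitude scaling and
#' is a pure function of its arguments: identical calls are
#' bit-identical.
#'
#' @param seed integer RNG seed.
#' @param size grid side in pixels (square field), at least 64.
#' @param cutoff isotropic low-pass cutoff in cycles/image; all spectral
#'   energy lies at radial frequencies <= `cutoff`.
#' @param relief_amplitude amplitude scale: the field is rescaled so its
#'   standard deviation equals this value (length units).
#' @param pixel_pitch length units per pixel.
#' @return A [height_field].
#' @examples
#' h <- generate_terrain(seed = 1, size = 64, cutoff = 8, relief_amplitude = 1)
#' range(h$heights)
#' @export
generate_terrain <- function(seed, size, cutoff, relief_amplitude = 1,
                             pixel_pitch = 1) {
  if (size < 64) stop_invalid("size must be >= 64")
  if (cutoff <= 0) stop_invalid("cutoff must be positive")
  if (relief_amplitude <= 0) stop_invalid("relief_amplitude must be positive")
  size <- as.integer(size)
  white <- with_seed(seed, matrix(rnorm(size * size), size, size))
  keep <- fft_radial_freq(size) <= cutoff
  keep[1, 1] <- FALSE                       # drop DC: zero mean by construction
  filt <- fft(white) * keep
  h <- Re(fft(filt, inverse = TRUE)) / (size * size)
  h <- h - mean(h)                          # kill numerical residue
  h <- h * (relief_amplitude / stats::sd(h))
  height_field(h, pixel_pitch = pixel_pitch, seed = as.integer(seed))
}

#' Clip a height field at a quantile floor and smooth
#'
#' Emulates clipped-noise terrain: heights below the value at quantile
#' `floor` are raised to it (creating flat valleys), then the field is
#' smoothed with a truncated Gaussian kernel.  Flat regions farther than
#' three sigma from any bump skirt remain exactly at the floor value.
#'
#' @param h a [height_field].
#' @param floor height quantile in `[0, 1]` at which to clip; 0 clips
#'   nothing, 1 flattens the field.
#' @param smooth_sigma Gaussian smoothing sigma in pixels (>= 0).
#' @return A [height_field].
#' @export
clip_and_smooth <- function(h, floor = 0.5, smooth_sigma = 2) {
  stopifnot(inherits(h, "height_field"))
  if (floor < 0 || floor > 1) stop_invalid("floor must be in [0, 1]")
  if (smooth_sigma < 0) stop_invalid("smooth_sigma must be non-negative")
  v <- stats::quantile(h$heights, probs = floor, names = FALSE, type = 1)
  clipped <- pmax(h$heights, v)
  height_field(gaussian_blur(clipped, smooth_sigma),
               pixel_pitch = h$pixel_pitch, seed = h$seed)
}

#' Cut depth achieving a target visible fraction
#'
#' Returns the height-quantile cut depth `d` such that the level-cut
#' mask of the requested polarity leaves fraction `f` of the pixels
#' visible (convex polarity: visible where `h >= d`; bistable: visible
#' where `h < d`).  The quantile is taken on the exact empirical
#' distribution of the sorted heights, with ties broken toward the
#' smaller depth, so the achieved fraction is within `1/size^2` of `f`.
#'
#' @param h a [height_field].
#' @param fraction target visible fraction, strictly between 0 and 1.
#' @param polarity `"convex"` (shaded peaks visible) or `"bistable"`
#'   (shaded valleys visible).
#' @return Cut depth `d` in height units.
#' @export
level_cut_depth_for_visibility <- function(h, fraction,
                                           polarity = c("convex", "bistable")) {
  stopifnot(inherits(h, "height_field"))
  polarity <- match.arg(polarity)
  if (fraction <= 0 || fraction >= 1) {
    stop_invalid("fraction must be strictly between 0 and 1")
  }
  hv <- sort(as.vector(h$heights))
  n <- length(hv)
  if (hv[1] == hv[n]) stop_invalid("no valid cut: height field is constant")
  # k = number of pixels that should be hidden below the cut
  k <- if (polarity == "convex") round((1 - fraction) * n) else round(fraction * n)
  # convex: visible = h >= d, want n - k visible -> d just above hv[k]
  # bistable: visible = h < d,  want k visible   -> same d
  k <- min(max(k, 1L), n - 1L)
  hv[k + 1L]
}

#' Build a level-cut mask from a height field
#'
#' Thresholds the height field at cut depth `d`.  Convex polarity masks
#' (occludes) everything behind the cut plane (`h < d`), leaving the
#' shaded peaks visible; bistable polarity masks everything in front
#' (`h >= d`), leaving the shaded valleys.  At the same `d` the two
#' polarities are exact logical complements.
#'
#' @param h a [height_field].
#' @param d cut depth (height units).
#' @param polarity `"convex"` or `"bistable"`.
#' @return An object of class `level_cut_mask`: list with `mask`
#'   (logical matrix, `TRUE` = occluded by the gray mask), `cut_depth`,
#'   `polarity`, `rotated`.
#' @export
make_level_cut_mask <- function(h, d, polarity = c("convex", "bistable")) {
  stopifnot(inherits(h, "height_field"))
  polarity <- match.arg(polarity)
  mask <- if (polarity == "convex") h$heights < d else h$heights >= d
  structure(list(mask = mask, cut_depth = d, polarity = polarity,
                 rotated = FALSE),
            class = "level_cut_mask")
}

#' @export
print.level_cut_mask <- function(x, ...) {
  cat(sprintf("<level_cut_mask> %d x %d, %s%s, d = %.4g, visible %.1f%%\n",
              nrow(x$mask), ncol(x$mask), x$polarity,
              if (x$rotated) " (rotated)" else "", x$cut_depth,
              100 * visible_fraction(x)))
  invisible(x)
}

#' Visible fraction of a level-cut mask
#'
#' @param m a `level_cut_mask`.
#' @return Fraction of pixels not covered by the mask.
#' @export
visible_fraction <- function(m) {
  stopifnot(inherits(m, "level_cut_mask"))
  1 - mean(m$mask)
}

#' Rotate a mask 180 degrees over the image
#'
#' Rotation about the image center destroys the geometric relation
#' between the mask contours and the underlying shading while leaving
#' contour shape and visible fraction unchanged.  Applying it twice
#' restores the original mask.
#'
#' @param m a `level_cut_mask`.
#' @return The rotated `level_cut_mask` with its `rotated` flag toggled.
#' @export
rotate_mask <- function(m) {
  stopifnot(inherits(m, "level_cut_mask"))
  m$mask <- m$mask[rev(seq_len(nrow(m$mask))), rev(seq_len(ncol(m$mask))),
                   drop = FALSE]
  m$rotated <- !m$rotated
  m
}
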