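# Ribbon stimuli: 2-px level-cut paths shaded as a linear function of
# orientation, optionally mixed with spectrum-matched noise.
#
# The linear shading rule assigns luminance
#   L = 0.8 - 0.6 * sep(theta, 90) / 180
# to a ribbon pixel with into-mask orientation theta, so luminance
# falls linearly from 0.8 at 90 deg (pointing up, toward the implied
# light) through 0.5 at exactly vertical segments (0 or 180 deg) to 0.2
# at 270 deg.  The background is exactly 0.5, the same value as
# vertical segments.  Cosine and linear falloffs correlate at 0.979
# over the quarter range, which is why the linear rule stands in for
# Lambert's law.

#' Linear orientation shading of ribbon pixels
#'
#' @param orientations into-mask ribbon orientations, degrees.
#' @return Luminance per pixel, decreasing linearly from 0.8 at 90
#'   degrees to 0.2 at 270 degrees (`NA` propagates).
#' @examples
#' linear_shade_ribbon(c(90, 0, 180, 270))  # 0.8 0.5 0.5 0.2
#' @export
linear_shade_ribbon <- function(orientations) {
  0.8 - 0.6 * angular_separation(orientations, 90) / 180
}

#' Radially averaged amplitude spectrum of a set of images
#'
#' Magnitudes of the discrete Fourier transform are averaged over
#' images and over annular frequency bins (integer-rounded radial
#' frequency, cycles/image).  The DC bin is excluded (set to zero).
#'
#' @param images list of [shaded_image]s (or numeric matrices) of a
#'   common square size.
#' @return Numeric vector of mean amplitudes indexed by radial
#'   frequency `0..floor(size/2)` (names give the frequency; entry "0"
#'   is 0).
#' @export
average_amplitude_spectrum <- function(images) {
  if (length(images) < 1) stop_invalid("need at least one image")
  mats <- lapply(images, function(im) {
    if (inherits(im, "shaded_image")) im$luminance else as.matrix(im)
  })
  sz <- dim(mats[[1]])
  if (sz[1] != sz[2]) stop_invalid("images must be square")
  if (!all(vapply(mats, function(m) all(dim(m) == sz), logical(1)))) {
    stop_invalid("images must share a common size")
  }
  n <- sz[1]
  fr <- round(fft_radial_freq(n))
  nyq <- floor(n / 2)
  acc <- numeric(nyq + 1)
  for (m in mats) {
    amp <- Mod(stats::fft(m))
    amp[1, 1] <- 0
    keep <- fr <= nyq
    acc <- acc + as.vector(tapply(amp[keep], fr[keep], mean))
  }
  out <- acc / length(mats)
  out[1] <- 0
  names(out) <- 0:nyq
  out
}

#' Synthesize noise matched to a target radial amplitude spectrum
#'
#' Seeded Gaussian white noise is Fourier transformed, its amplitudes
#' replaced by the target profile interpolated at each frequency's
#' radius (phases kept, which preserves conjugate symmetry), and
#' inverse transformed.  The measured radial spectrum of the output
#' therefore matches the target up to annular binning error.
#'
#' @param target_spectrum non-negative radial amplitude profile indexed
#'   by integer frequency from 0 (as returned by
#'   [average_amplitude_spectrum]).
#' @param size output side in pixels.
#' @param seed integer RNG seed.
#' @return An object of class `noise_texture`: list with `values`
#'   (matrix), `target_spectrum`, `seed`.
#' @export
spectrum_matched_noise <- function(target_spectrum, size, seed) {
  if (any(target_spectrum < 0)) stop_invalid("spectrum must be non-negative")
  size <- as.integer(size)
  white <- with_seed(seed, matrix(rnorm(size * size), size, size))
  W <- stats::fft(white)
  modW <- Mod(W)
  phase <- W / ifelse(modW == 0, 1, modW)   # unit-modulus, conjugate-symmetric
  fr <- fft_radial_freq(size)
  prof_f <- suppressWarnings(as.numeric(names(target_spectrum)))
  if (length(prof_f) != length(target_spectrum) || anyNA(prof_f)) {
    prof_f <- seq_along(target_spectrum) - 1
  }
  amp <- matrix(stats::approx(prof_f, target_spectrum, xout = pmin(fr, max(prof_f)),
                              rule = 2)$y, size, size)
  amp[1, 1] <- 0
  vals <- Re(stats::fft(amp * phase, inverse = TRUE)) / (size * size)
  structure(list(values = vals, target_spectrum = target_spectrum,
                 seed = as.integer(seed)), class = "noise_texture")
}

#' Mix linear ribbon shading with noise
#'
#' Noise samples along the ribbon are affinely rescaled to span
#' `[0.2, 0.8]` (the gamut of the noiseless shading), then mixed
#' per-pixel: `L = (1 - w) * shaded + w * noise`.
#'
#' @param shaded luminances from [linear_shade_ribbon].
#' @param noise noise values sampled on the ribbon path (any scale).
#' @param w noise proportion in `[0, 1]`.
#' @return Mixed luminances in `[0.2, 0.8]`.
#' @export
mix_ribbon <- function(shaded, noise, w) {
  if (w < 0 || w > 1) stop_invalid("noise proportion w must be in [0, 1]")
  if (w == 0) return(shaded)
  rng <- range(noise, na.rm = TRUE)
  scaled <- if (diff(rng) == 0) rep(0.5, length(noise)) else {
    0.2 + 0.6 * (noise - rng[1]) / diff(rng)
  }
  (1 - w) * shaded + w * scaled
}

#' Packaged default noise target spectrum
#'
#' Radially averaged amplitude spectrum of 16 seeded rendered terrains
#' (256 px, band limit 8 cycles/image), shipped as a fixture so ribbon
#' generation needs no rendering step.  Absolute amplitude scale is
#' irrelevant downstream because [mix_ribbon] rescales noise to the
#' shading gamut.
#'
#' @return Named numeric amplitude profile indexed by radial frequency.
#' @export
default_ribbon_spectrum <- function() {
  d <- utils::read.csv(system.file("extdata", "default_ribbon_spectrum.csv",
                                   package = "levelcut"))
  stats::setNames(d$amplitude, d$frequency)
}

#' Noise proportions used for paper-faithful ribbon runs
#'
#' The 13 mixing proportions, chosen (non-uniformly) to yield an
#' approximately uniform distribution of measured correlations.
#'
#' @return Numeric vector of length 13.
#' @export
ribbon_noise_levels <- function() {
  c(0, 0.15, 0.30, 0.35, 0.40, 0.45, 0.50, 0.55, 0.60, 0.65, 0.70, 0.85, 1.0)
}

#' Compose a ribbon image on a gray background
#'
#' Fills the background with exactly 0.5 and draws each ribbon pixel at
#' its luminance.  Width-2 realization: the path pixel plus its
#' neighbor one step along the into-mask normal.  8-bit quantization,
#' when requested, is the last step.
#'
#' @param positions ribbon path positions (data frame `x`, `y`).
#' @param orientations into-mask orientations (degrees; used to place
#'   the second-width pixel).
#' @param luminances per-path-pixel luminances.
#' @param size image side in pixels.
#' @param width ribbon width in pixels (1 or 2; default 2).
#' @param background background luminance (default 0.5).
#' @param bit_depth `"float"` or `8`.
#' @return A [shaded_image].
#' @export
compose_ribbon_image <- function(positions, orientations, luminances, size,
                                 width = 2, background = 0.5,
                                 bit_depth = "float") {
  size <- as.integer(size)
  L <- matrix(background, size, size)
  ok <- !is.na(luminances)
  x <- positions$x[ok]; y <- positions$y[ok]
  lum <- luminances[ok]; ori <- orientations[ok]
  if (any(x < 1 | x > size | y < 1 | y > size)) {
    stop_invalid("ribbon path falls outside the image")
  }
  L[cbind(y, x)] <- lum
  if (width >= 2) {
    x2 <- as.integer(round(x + cos(deg2rad(ori))))
    y2 <- as.integer(round(y - sin(deg2rad(ori))))
    keep <- !is.na(ori) & x2 >= 1 & x2 <= size & y2 >= 1 & y2 <= size
    L[cbind(y2[keep], x2[keep])] <- lum[keep]
  }
  L <- quantize_luminance(pmin(pmax(L, 0), 1), bit_depth)
  shaded_image(L, bit_depth = bit_depth)
}

#' Generate a complete ribbon stimulus
#'
#' End-to-end ribbon synthesis: a seeded terrain is cut at 50%
#' visibility, the level-cut contour path and its into-mask
#' orientations are extracted, the path is shaded with the linear rule,
#' mixed with spectrum-matched noise in proportion `w`, and composed on
#' a 0.5 gray background.  The measured covariation of the result
#' (sampling the contour path itself, inset 0) is attached.
#'
#' @param seed integer seed (drives terrain and noise independently).
#' @param size image side in pixels.
#' @param noise_proportion mixing proportion `w` in `[0, 1]`.
#' @param cutoff terrain band limit, cycles/image (default 8).
#' @param target_spectrum radial amplitude profile for the noise;
#'   default `NULL` uses the packaged [default_ribbon_spectrum].
#' @param measure if `TRUE` (default) run the measurement pipeline and
#'   attach the `covariation` result.
#' @return A list of class `ribbon_stimulus`: `image` ([shaded_image]),
#'   `path` (data frame `x`, `y`, `orientation_deg`, `shaded`, `mixed`),
#'   `w`, `seed`, and `measured` (a `covariation` or `NULL`).
#' @export
ribbon_stimulus <- function(seed, size = 256, noise_proportion = 0,
                            cutoff = 8, target_spectrum = NULL,
                            measure = TRUE) {
  h <- generate_terrain(seed = seed, size = size, cutoff = cutoff)
  d <- level_cut_depth_for_visibility(h, 0.5, "convex")
  m <- make_level_cut_mask(h, d, "convex")
  pos <- extract_contour_pixels(m)
  tang <- estimate_orientation_180(pos)
  ori <- disambiguate_orientation_360(m, pos, tang)
  keep <- !is.na(ori)
  pos <- pos[keep, , drop = FALSE]; ori <- ori[keep]
  shaded <- linear_shade_ribbon(ori)
  if (noise_proportion > 0) {
    if (is.null(target_spectrum)) {
      target_spectrum <- default_ribbon_spectrum()
    }
    nt <- spectrum_matched_noise(target_spectrum, size, seed = seed + 1L)
    noise_on_path <- nt$values[cbind(pos$y, pos$x)]
    mixed <- mix_ribbon(shaded, noise_on_path, noise_proportion)
  } else {
    mixed <- shaded
  }
  img <- compose_ribbon_image(pos, ori, mixed, size = size)
  measured <- NULL
  if (measure) {
    cp <- measure_contour(img, m, inset = 0)
    measured <- covariation_score(cp)
  }
  structure(list(image = img,
                 path = data.frame(x = pos$x, y = pos$y,
                                   orientation_deg = ori, shaded = shaded,
                                   mixed = mixed),
                 w = noise_proportion, seed = as.integer(seed),
                 measured = measured),
            class = "ribbon_stimulus")
}

#' @export
print.ribbon_stimulus <- function(x, ...) {
  cat(sprintf("<ribbon_stimulus> seed %d, w = %.2f, %d path pixels",
              x$seed, x$w, nrow(x$path)))
  if (!is.null(x$measured)) {
    cat(sprintf(", measured rho = %.3f at %g deg",
                x$measured$rho, x$measured$best_azimuth))
  }
  cat("\n")
  invisible(x)
}
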