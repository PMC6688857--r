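# The orientation-intensity covariation statistic.
#
# For a candidate illumination azimuth a, each contour pixel's
# orientation is converted to its angular separation from a; the
# Pearson correlation between separation and intensity, negated so that
# shading-like falloff (intensity decreasing with separation) scores
# +1, is the per-azimuth covariation.  The final score rho is the
# maximum over 16 candidate azimuths (0 to 337.5 in 22.5-degree steps),
# guarding against incidental correlations consistent with other light
# directions.  A cosine fit of intensity on orientation summarises the
# falloff in the form L ~ A + B cos(theta - C).

#' Angular separation between an orientation and an azimuth
#'
#' Circular absolute difference, in degrees `[0, 180]`.
#'
#' @param theta orientation(s) in degrees.
#' @param azimuth reference azimuth in degrees.
#' @return Separation(s) in `[0, 180]`.
#' @export
angular_separation <- function(theta, azimuth) {
  circ_diff(theta, azimuth)
}

#' Per-azimuth Pearson covariation
#'
#' Negated Pearson correlation between angular separation from
#' `azimuth` and intensity, over the valid contour pixels, so a perfect
#' shading-like falloff scores +1.
#'
#' @param pixels a `contour_pixels` data frame ([measure_contour]) or
#'   any data frame with `orientation_deg`, `intensity` and optionally
#'   `valid` columns.
#' @param azimuth candidate illumination azimuth, degrees.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_covariation <- function(pixels, azimuth) {
  v <- valid_pixels(pixels)
  if (nrow(v) < 3) stop_invalid("need at least 3 valid contour pixels")
  sep <- angular_separation(v$orientation_deg, azimuth)
  if (stats::sd(sep) == 0 || stats::sd(v$intensity) == 0) {
    stop_invalid("undefined correlation: zero variance in separation or intensity")
  }
  -stats::cor(sep, v$intensity)
}

valid_pixels <- function(pixels) {
  if (!is.null(pixels$valid)) pixels <- pixels[pixels$valid, , drop = FALSE]
  pixels[!is.na(pixels$orientation_deg) & !is.na(pixels$intensity), ,
         drop = FALSE]
}

#' Covariation score with the 16-azimuth maximum rule
#'
#' Computes the per-azimuth Pearson covariation on a grid of candidate
#' illumination azimuths and takes the maximum as the final score rho;
#' ties go to the smallest azimuth.  A cosine fit ([cosine_fit]) of
#' intensity on orientation is attached when it is well defined.
#'
#' @param pixels a `contour_pixels` data frame.
#' @param azimuths candidate azimuths in degrees (default 0, 22.5, ...,
#'   337.5).
#' @return An object of class `covariation`: list with `per_azimuth_r`
#'   (named numeric, one entry per azimuth), `best_azimuth`, `rho`,
#'   `n_pixels`, and `cosine_fit` (a `cosine_fit` result or `NULL`).
#' @examples
#' px <- data.frame(orientation_deg = seq(0, 350, by = 10))
#' px$intensity <- 0.8 - 0.6 * angular_separation(px$orientation_deg, 90) / 180
#' covariation_score(px)
#' @export
covariation_score <- function(pixels, azimuths = seq(0, 337.5, by = 22.5)) {
  r <- vapply(azimuths, function(a) pearson_covariation(pixels, a), numeric(1))
  names(r) <- format(azimuths, trim = TRUE)
  best <- which.max(r)             # which.max returns the first (smallest) tie
  cf <- tryCatch(cosine_fit(pixels), error = function(e) NULL)
  structure(list(per_azimuth_r = r,
                 best_azimuth = azimuths[best],
                 rho = unname(r[best]),
                 n_pixels = nrow(valid_pixels(pixels)),
                 cosine_fit = cf),
            class = "covariation")
}

#' @export
print.covariation <- function(x, ...) {
  cat(sprintf("<covariation> rho = %.3f at azimuth %g deg (n = %d pixels)\n",
              x$rho, x$best_azimuth, x$n_pixels))
  if (!is.null(x$cosine_fit)) {
    cat(sprintf("  cosine fit: A = %.3f, B = %.3f, C = %.1f deg, r = %.3f, p = %.3g\n",
                x$cosine_fit$falloff$offset, x$cosine_fit$falloff$amplitude,
                x$cosine_fit$falloff$phase, x$cosine_fit$r, x$cosine_fit$p))
  }
  invisible(x)
}

#' @export
coef.covariation <- function(object, ...) {
  c(rho = object$rho, best_azimuth = object$best_azimuth)
}

#' @export
plot.covariation <- function(x, ...) {
  az <- as.numeric(names(x$per_azimuth_r))
  graphics::plot(az, x$per_azimuth_r, type = "b", xlab = "azimuth (deg)",
                 ylab = "covariation r", ylim = c(-1, 1), ...)
  graphics::abline(v = x$best_azimuth, lty = 2)
  invisible(x)
}

#' Least-squares cosine fit of intensity on orientation
#'
#' Fits `I ~ A + B cos(theta - C)` by the linearization
#' `I ~ A + u cos(theta) + v sin(theta)` with `B = sqrt(u^2 + v^2)` and
#' `C = atan2(v, u)`.  The fit correlation is the Pearson correlation
#' between fitted and observed intensities; its p-value uses the
#' two-sided t approximation with n - 2 degrees of freedom and is
#' descriptive only (neighboring contour pixels are spatially
#' autocorrelated).
#'
#' @param pixels a `contour_pixels` data frame with at least 4 valid
#'   pixels.
#' @return A list with `falloff` (a [cosine_falloff]), `r`, `p`, `n`.
#' @export
cosine_fit <- function(pixels) {
  v <- valid_pixels(pixels)
  if (nrow(v) < 4) stop_invalid("need at least 4 valid contour pixels")
  th <- deg2rad(v$orientation_deg)
  fit <- stats::lm(v$intensity ~ cos(th) + sin(th))
  u <- unname(coef(fit)[2]); w <- unname(coef(fit)[3])
  B <- sqrt(u^2 + w^2)
  if (!is.finite(B) || B < 1e-12 || stats::sd(fitted(fit)) < 1e-12) {
    stop_invalid("degenerate cosine fit: no orientation dependence")
  }
  r <- stats::cor(fitted(fit), v$intensity)
  n <- nrow(v)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(falloff = cosine_falloff(amplitude = B, offset = unname(coef(fit)[1]),
                                phase = wrap360(rad2deg(atan2(w, u)))),
       r = r, p = p, n = n)
}

#' Correlation between cosine and linear falloff
#'
#' The Pearson correlation between `cos(theta)` and `theta` over a
#' dense uniform grid of angular separations `[0, max_separation]`.
#' Over the quarter range (0 to 90 degrees) the magnitude is 0.979,
#' which justifies approximating the Lambertian cosine falloff with a
#' linear one when scoring ribbon stimuli; over the full 0-180 range it
#' is 0.993.
#'
#' @param max_separation upper end of the separation range, degrees.
#' @param n grid resolution (default 100001).
#' @return Correlation magnitude in `[0, 1]`.
#' @export
cosine_linear_correlation <- function(max_separation = 90, n = 100001) {
  th <- seq(0, max_separation, length.out = n)
  abs(stats::cor(cos(deg2rad(th)), th))
}
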