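# Serialization: height fields as 16-bit TIFF with a JSON sidecar,
# masks as 0/255 PNG, images as 8-bit PNG or 16-bit TIFF, contour
# pixel sets as CSV, covariation results as JSON.

#' Write a height field as 16-bit grayscale TIFF with JSON sidecar
#'
#' Heights are linearly mapped to `[0, 1]`; the offset/scale needed to
#' recover the original values is recorded in `<path>.json`.
#'
#' @param h a [height_field].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_height_field <- function(h, path) {
  stopifnot(inherits(h, "height_field"))
  rng <- range(h$heights)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  tiff::writeTIFF((h$heights - rng[1]) / scale, path, bits.per.sample = 16)
  jsonlite::write_json(
    list(offset = rng[1], scale = scale, pixel_pitch = h$pixel_pitch,
         seed = h$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a height field written by [write_height_field]
#'
#' @param path TIFF path (sidecar `<path>.json` must exist).
#' @return A [height_field].
#' @export
read_height_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  height_field(m * meta$scale + meta$offset, pixel_pitch = meta$pixel_pitch,
               seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
}

#' Write a level-cut mask as a 0/255 PNG
#'
#' @param m a `level_cut_mask`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(m, path) {
  stopifnot(inherits(m, "level_cut_mask"))
  png::writePNG(m$mask * 1, path)
  invisible(path)
}

#' Read a 0/255 PNG as a level-cut mask
#'
#' @param path PNG path.
#' @param cut_depth,polarity metadata to attach (not stored in the
#'   PNG).
#' @return A `level_cut_mask`.
#' @export
read_mask_png <- function(path, cut_depth = NA_real_, polarity = "convex") {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  structure(list(mask = m > 0.5, cut_depth = cut_depth, polarity = polarity,
                 rotated = FALSE),
            class = "level_cut_mask")
}

#' Write a shaded image to PNG (8-bit) or TIFF (16-bit)
#'
#' @param img a [shaded_image].
#' @param path output path; `.png` writes 8-bit, `.tif`/`.tiff` writes
#'   16-bit.
#' @return `path`, invisibly.
#' @export
write_shaded_image <- function(img, path) {
  stopifnot(inherits(img, "shaded_image"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img$luminance, path)
  } else {
    tiff::writeTIFF(img$luminance, path, bits.per.sample = 16)
  }
  invisible(path)
}

#' Write a contour pixel set as CSV
#'
#' Columns: `x`, `y`, `orientation_deg`, `intensity`, `valid`.
#'
#' @param pixels a `contour_pixels` data frame ([measure_contour]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(pixels, path) {
  utils::write.csv(as.data.frame(pixels), path, row.names = FALSE)
  invisible(path)
}

#' Read a contour pixel set from CSV
#'
#' @param path CSV path written by [write_contour_csv].
#' @return A `contour_pixels` data frame.
#' @export
read_contour_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("contour_pixels", "data.frame")
  out
}

#' Write a covariation result as JSON
#'
#' Records the per-azimuth table and the summary (rho, best azimuth,
#' pixel count, cosine-fit parameters).
#'
#' @param x a `covariation` ([covariation_score]).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_covariation_json <- function(x, path) {
  stopifnot(inherits(x, "covariation"))
  rec <- list(
    per_azimuth = list(azimuth = as.numeric(names(x$per_azimuth_r)),
                       r = unname(x$per_azimuth_r)),
    rho = x$rho, best_azimuth = x$best_azimuth, n_pixels = x$n_pixels)
  if (!is.null(x$cosine_fit)) {
    rec$cosine_fit <- list(amplitude = x$cosine_fit$falloff$amplitude,
                           offset = x$cosine_fit$falloff$offset,
                           phase = x$cosine_fit$falloff$phase,
                           r = x$cosine_fit$r, p = x$cosine_fit$p)
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
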