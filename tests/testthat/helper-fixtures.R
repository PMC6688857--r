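# Analytic fixtures built in code: hemispheres, ramps, disc and
# half-plane masks, and small convenience oracles.

# Hemisphere of radius R (pixels) centered in an n x n grid.
make_hemisphere <- function(n, R) {
  rowm <- matrix(seq_len(n), n, n)
  colm <- t(rowm)
  cx <- (n + 1) / 2
  r2 <- (rowm - cx)^2 + (colm - cx)^2
  height_field(sqrt(pmax(R^2 - r2, 0)))
}

# Linear ramp increasing along columns (rightward).
make_ramp <- function(n) {
  height_field(matrix(rep(seq_len(n), each = n), n, n, byrow = TRUE))
}

# Bare mask object from a logical matrix.
mask_from_matrix <- function(mat, polarity = "convex") {
  structure(list(mask = mat, cut_depth = NA_real_, polarity = polarity,
                 rotated = FALSE),
            class = "level_cut_mask")
}

# Disc-shaped mask (TRUE inside the disc) centered in an n x n grid.
disc_mask <- function(n, R) {
  rowm <- matrix(seq_len(n), n, n)
  colm <- t(rowm)
  cx <- (n + 1) / 2
  mask_from_matrix((rowm - cx)^2 + (colm - cx)^2 <= R^2)
}

# Half-plane mask: TRUE for rows >= k (the lower part of the image).
half_plane_mask <- function(n, k) {
  rowm <- matrix(seq_len(n), n, n)
  mask_from_matrix(rowm >= k)
}

# Circular absolute difference in degrees.
circ_err <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Contour-pixel data frame from raw vectors.
pixels_df <- function(orientation, intensity) {
  data.frame(orientation_deg = orientation, intensity = intensity,
             valid = TRUE)
}
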