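# High-level stimulus batteries combining the synthesis modules.

#' Generate and measure a level-cut stimulus battery
#'
#' Builds the 12-stimulus design crossing three gradient-visibility
#' fractions (25%, 50%, 75%) with four mask conditions: convex level
#' cut, bistable level cut, and their 180-degree-rotated controls.  A
#' single seeded terrain is rendered once; each mask is composited at
#' the mean gray and the orientation-intensity covariation of the
#' resulting contours is measured.  Rotation preserves contour shape
#' but breaks the geometric relation to the shading, so rotated
#' conditions should measure low rho while level-cut conditions measure
#' high rho.
#'
#' The `convex_fraction` column carries the design convexity value used
#' by the synthetic observer (1 for convex level cuts, 0.5 for
#' bistable, 0.25 for rotated masks, whose gradients mostly appear as
#' neither bumps nor dents).
#'
#' @param seed integer seed for the terrain.
#' @param size image side in pixels (default 256).
#' @param cutoff terrain band limit, cycles/image (default 8).
#' @param fractions visible-gradient fractions (default 0.25, 0.5,
#'   0.75).
#' @return A data frame of class `stimulus_battery` with one row per
#'   stimulus: `condition`, `visibility`, `rotated`, `rho`,
#'   `best_azimuth`, `n_pixels`, `convex_fraction`, and a `stimuli`
#'   attribute holding the masked [shaded_image]s.
#' @export
level_cut_battery <- function(seed, size = 256, cutoff = 8,
                              fractions = c(0.25, 0.5, 0.75)) {
  h <- generate_terrain(seed = seed, size = size, cutoff = cutoff)
  img <- render_height_field(h)
  rows <- list(); imgs <- list(); k <- 0L
  for (f in fractions) {
    for (pol in c("convex", "bistable")) {
      d <- level_cut_depth_for_visibility(h, f, pol)
      base <- make_level_cut_mask(h, d, pol)
      for (rot in c(FALSE, TRUE)) {
        m <- if (rot) rotate_mask(base) else base
        masked <- apply_mask(img, m, gray = "mean")
        cp <- measure_contour(masked, m)
        cs <- covariation_score(cp)
        k <- k + 1L
        rows[[k]] <- data.frame(
          condition = if (rot) paste0("rotated_", pol) else pol,
          visibility = f, rotated = rot, rho = cs$rho,
          best_azimuth = cs$best_azimuth, n_pixels = cs$n_pixels,
          convex_fraction = if (rot) 0.25 else if (pol == "convex") 1 else 0.5)
        imgs[[k]] <- masked
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "stimuli") <- imgs
  class(out) <- c("stimulus_battery", "data.frame")
  out
}
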