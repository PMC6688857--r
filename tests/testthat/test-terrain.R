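test_that("terrain generation is seeded, deterministic and band-limited", {
  h1 <- generate_terrain(seed = 1, size = 128, cutoff = 8)
  h2 <- generate_terrain(seed = 1, size = 128, cutoff = 8)
  expect_identical(h1$heights, h2$heights)
  h3 <- generate_terrain(seed = 2, size = 128, cutoff = 8)
  expect_false(identical(h1$heights, h3$heights))

  expect_equal(mean(h1$heights), 0, tolerance = 1e-10)
  expect_equal(sd(h1$heights), 1, tolerance = 1e-10)

  # independent DFT oracle: energy fraction at radial frequencies <= cutoff
  amp2 <- Mod(fft(h1$heights))^2
  fr <- sqrt(outer(c(0:64, -63:-1)^2, c(0:64, -63:-1)^2, "+"))
  expect_gte(sum(amp2[fr <= 8]) / sum(amp2), 0.99)

  expect_error(generate_terrain(1, 32, 8), "size")
  expect_error(generate_terrain(1, 128, -1), "cutoff")
  expect_error(generate_terrain(1, 128, 8, relief_amplitude = 0), "amplitude")
})

test_that("clip_and_smooth clips at the floor quantile then smooths", {
  h <- generate_terrain(seed = 3, size = 128, cutoff = 8)

  # floor = 0: no clipping, output equals smoothed input
  ref <- clip_and_smooth(height_field(h$heights), floor = 0, smooth_sigma = 0)
  expect_equal(ref$heights, h$heights)

  # floor = 1: constant field
  flat <- clip_and_smooth(h, floor = 1, smooth_sigma = 1)
  expect_equal(max(flat$heights) - min(flat$heights), 0, tolerance = 1e-12)

  # floor = 0.5 on a symmetric zero-mean field: ~50% of pixels at the
  # floor value before smoothing (count with the median oracle)
  c0 <- clip_and_smooth(h, floor = 0.5, smooth_sigma = 0)
  med <- median(h$heights)
  v <- min(c0$heights)              # the realized floor value
  expect_equal(mean(c0$heights == v), 0.5, tolerance = 0.01)
  expect_lt(abs(v - med), 0.01 * sd(h$heights))

  # far-field flats stay exactly at floor: clip a lone bump
  z <- matrix(0, 64, 64); z[32, 32] <- 5
  cb <- clip_and_smooth(height_field(z), floor = 0, smooth_sigma = 2)
  expect_equal(cb$heights[1, 1], 0)

  expect_error(clip_and_smooth(h, floor = 0.5, smooth_sigma = -1), "sigma")
})

test_that("cut depth for a target visibility matches the sorted-quantile oracle", {
  h <- make_ramp(64)
  d <- level_cut_depth_for_visibility(h, 0.5, "convex")
  expect_equal(d, sort(as.vector(h$heights))[64 * 64 / 2 + 1])
  m <- make_level_cut_mask(h, d, "convex")
  expect_lte(abs(visible_fraction(m) - 0.5), 1 / 64^2)

  # f -> 1 convex: cut near the minimum, mask nearly empty
  d1 <- level_cut_depth_for_visibility(h, 0.999, "convex")
  m1 <- make_level_cut_mask(h, d1, "convex")
  expect_lte(mean(m1$mask), 0.002)

  # convex f = 0.25 and bistable f = 0.75 share the cut depth
  hh <- generate_terrain(seed = 4, size = 128, cutoff = 8)
  expect_equal(level_cut_depth_for_visibility(hh, 0.25, "convex"),
               level_cut_depth_for_visibility(hh, 0.75, "bistable"))

  expect_error(level_cut_depth_for_visibility(height_field(matrix(1, 64, 64)),
                                              0.5, "convex"), "constant")
  expect_error(level_cut_depth_for_visibility(h, 0, "convex"), "fraction")
})

test_that("quantile accuracy and complementarity hold across seeds and fractions", {
  for (seed in 1:3) {
    h <- generate_terrain(seed = seed, size = 128, cutoff = 8)
    for (f in c(0.25, 0.5, 0.75)) {
      for (pol in c("convex", "bistable")) {
        d <- level_cut_depth_for_visibility(h, f, pol)
        m <- make_level_cut_mask(h, d, pol)
        expect_lte(abs(visible_fraction(m) - f), 1 / 128^2)
      }
      d <- level_cut_depth_for_visibility(h, f, "convex")
      cv <- make_level_cut_mask(h, d, "convex")
      bi <- make_level_cut_mask(h, d, "bistable")
      expect_identical(cv$mask, !bi$mask)  # exact complements at equal d
    }
  }
})

test_that("visible fraction of the convex mask is non-increasing in cut depth", {
  h <- generate_terrain(seed = 5, size = 128, cutoff = 8)
  ds <- quantile(h$heights, seq(0.1, 0.9, by = 0.1))
  vis <- sapply(ds, function(d) visible_fraction(make_level_cut_mask(h, d, "convex")))
  expect_true(all(diff(vis) <= 0))
})

test_that("mask geometry: boundary-depth edge case and hemisphere disc cut", {
  h <- make_ramp(64)
  m <- make_level_cut_mask(h, min(h$heights) - 1, "convex")
  expect_false(any(m$mask))   # cut behind everything: nothing occluded

  # hemisphere cut at half height: visible region is the analytic disc
  hs <- make_hemisphere(128, R = 50)
  d <- 25
  m2 <- make_level_cut_mask(hs, d, "convex")
  analytic <- pi * (50^2 - d^2)     # area of the disc r = sqrt(R^2 - d^2)
  expect_equal(sum(!m2$mask), analytic, tolerance = 0.02)
})

test_that("180-degree mask rotation is an involution preserving coverage", {
  h <- generate_terrain(seed = 6, size = 128, cutoff = 8)
  d <- level_cut_depth_for_visibility(h, 0.5, "convex")
  m <- make_level_cut_mask(h, d, "convex")
  r <- rotate_mask(m)
  expect_true(r$rotated)
  expect_equal(visible_fraction(r), visible_fraction(m))
  rr <- rotate_mask(r)
  expect_identical(rr$mask, m$mask)
  expect_false(rr$rotated)

  # centrally symmetric mask is unchanged by rotation
  dm <- disc_mask(65, 20)
  expect_identical(rotate_mask(dm)$mask, dm$mask)
})
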