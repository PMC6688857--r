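test_that("contour extraction returns the gradient-side boundary", {
  # 1-pixel mask dot: its 8 neighbors
  dot <- matrix(FALSE, 9, 9); dot[5, 5] <- TRUE
  pos <- extract_contour_pixels(mask_from_matrix(dot))
  expect_equal(nrow(pos), 8)
  expect_true(all(abs(pos$x - 5) <= 1 & abs(pos$y - 5) <= 1))
  expect_false(any(pos$x == 5 & pos$y == 5))

  # half-plane mask on rows >= k: contour is row k - 1
  pos2 <- extract_contour_pixels(half_plane_mask(16, 10))
  expect_true(all(pos2$y == 9))
  expect_equal(nrow(pos2), 16)

  # disc mask radius R: boundary ring, counted by an independent
  # brute-force rasterized-circle oracle
  dm <- disc_mask(129, 40)
  oracle <- 0L
  for (r in 1:129) for (c in 1:129) {
    if (!dm$mask[r, c]) {
      nb <- dm$mask[max(1, r - 1):min(129, r + 1), max(1, c - 1):min(129, c + 1)]
      if (any(nb)) oracle <- oracle + 1L
    }
  }
  pos3 <- extract_contour_pixels(dm)
  expect_equal(nrow(pos3), oracle)
  # and of the order of the circumference (8-connected outer ring is
  # somewhat thicker than the ideal 2*pi*R line)
  expect_lt(abs(nrow(pos3) - 2 * pi * 40) / (2 * pi * 40), 0.4)

  expect_error(extract_contour_pixels(mask_from_matrix(matrix(TRUE, 4, 4))),
               "uniform")
})

test_that("local-PCA tangents recover straight and circular contours", {
  n <- 32
  horiz <- data.frame(x = 1:n, y = rep(10, n))
  th <- estimate_orientation_180(horiz)
  expect_true(all(abs(th) < 1e-6))

  diag_up <- data.frame(x = 1:n, y = n:1)  # up-rightward on screen
  td <- estimate_orientation_180(diag_up)
  expect_true(all(abs(td - 45) < 1e-6))

  # circle of radius 100: tangent at polar angle phi is phi + 90 (mod 180)
  pos <- extract_contour_pixels(disc_mask(257, 100))
  tang <- estimate_orientation_180(pos)
  phi <- atan2(-(pos$y - 129), pos$x - 129) * 180 / pi
  truth <- (phi + 90) %% 180
  err <- pmin(abs(tang - truth) %% 180, 180 - abs(tang - truth) %% 180)
  expect_lt(mean(err, na.rm = TRUE), 5)

  expect_error(estimate_orientation_180(horiz, window = 4), "window")
  # isolated pixels are flagged invalid, not errored
  sparse <- data.frame(x = c(1, 30), y = c(1, 30))
  expect_true(all(is.na(estimate_orientation_180(sparse))))
})

test_that("side probing disambiguates tangents into into-mask normals", {
  # mask fills the lower half: normals point down (270 degrees)
  m <- half_plane_mask(32, 17)
  pos <- extract_contour_pixels(m)
  tang <- estimate_orientation_180(pos)
  ori <- disambiguate_orientation_360(m, pos, tang)
  expect_true(all(abs(ori - 270) < 1e-6, na.rm = TRUE))
  expect_lt(mean(is.na(ori)), 0.2)

  # disc mask: normals point toward the disc center (phi + 180)
  dm <- disc_mask(257, 100)
  posd <- extract_contour_pixels(dm)
  orid <- disambiguate_orientation_360(dm, posd, estimate_orientation_180(posd))
  phi <- atan2(-(posd$y - 129), posd$x - 129) * 180 / pi
  truth <- (phi + 180) %% 360
  expect_lt(mean(circ_err(orid, truth), na.rm = TRUE), 5)

  # 180-degree mask rotation flips every normal by 180
  h <- generate_terrain(seed = 9, size = 128, cutoff = 8)
  d <- level_cut_depth_for_visibility(h, 0.5, "convex")
  mk <- make_level_cut_mask(h, d, "convex")
  p1 <- extract_contour_pixels(mk)
  o1 <- disambiguate_orientation_360(mk, p1, estimate_orientation_180(p1))
  rk <- rotate_mask(mk)
  p2 <- extract_contour_pixels(rk)
  o2 <- disambiguate_orientation_360(rk, p2, estimate_orientation_180(p2))
  # match rotated positions back to originals
  key1 <- paste(p1$x, p1$y)
  key2 <- paste(129 - p2$x, 129 - p2$y)
  idx <- match(key2, key1)
  ok <- !is.na(idx) & !is.na(o2) & !is.na(o1[idx])
  expect_gt(mean(ok), 0.9)
  expect_lt(mean(circ_err(o2[ok], (o1[idx][ok] + 180) %% 360)), 1)
})

test_that("adjacent-intensity sampling reads the gradient side", {
  uni <- shaded_image(matrix(0.42, 32, 32))
  m <- half_plane_mask(32, 17)
  pos <- extract_contour_pixels(m)
  ori <- rep(270, nrow(pos))
  expect_true(all(sample_adjacent_intensity(uni, pos, ori) == 0.42))

  # vertical luminance ramp under a lower-half mask: inset-1 samples are
  # one row above the contour row
  ramp <- shaded_image(matrix(rep((1:32) / 32, 32), 32, 32))
  got <- sample_adjacent_intensity(ramp, pos, ori, inset = 1)
  expect_true(all(got == 15 / 32))

  # probes that leave the image are flagged invalid
  top <- data.frame(x = 16, y = 1)
  expect_true(is.na(sample_adjacent_intensity(uni, top, 270, inset = 3)))
})

test_that("hemisphere rim intensities follow the clipped rim cosine", {
  h <- make_hemisphere(256, R = 100)
  img <- render_height_field(h, collimated_light(90, 45, 5))
  m <- make_level_cut_mask(h, 1e-9, "convex")  # mask = background plane
  cp <- measure_contour(img, m, inset = 2)
  v <- cp[cp$valid, ]
  pred <- rim_luminance(v$orientation_deg, cosine_falloff(1, phase = 90))
  expect_gt(cor(v$intensity, pred), 0.99)
})

test_that("ground-truth tilt is the direction of steepest descent", {
  # plane rising toward the bottom of the screen: downhill is up-screen
  h <- height_field(matrix(rep(1:32, 32), 32, 32))  # h increases with row
  gt <- ground_truth_tilt(h)
  expect_true(all(abs(gt - 90) < 1e-9))

  # radial bump: tilt points radially outward from the peak
  hb <- make_hemisphere(65, 25)
  gtb <- ground_truth_tilt(hb)
  inside <- which(hb$heights > 1 & hb$heights < 24, arr.ind = TRUE)
  outward <- (atan2(-(inside[, 1] - 33), inside[, 2] - 33) * 180 / pi) %% 360
  expect_lt(mean(circ_err(gtb[inside], outward)), 3)
})

test_that("estimated rim orientations agree with the gradient oracle on terrains", {
  errs <- c(); invalid <- c(); hit15 <- c()
  for (seed in c(11, 12, 13)) {
    h <- generate_terrain(seed = seed, size = 256, cutoff = 8)
    d <- level_cut_depth_for_visibility(h, 0.5, "convex")
    m <- make_level_cut_mask(h, d, "convex")
    pos <- extract_contour_pixels(m)
    ori <- disambiguate_orientation_360(m, pos, estimate_orientation_180(pos))
    gt <- ground_truth_tilt(h)[cbind(pos$y, pos$x)]
    ok <- !is.na(ori) & !is.na(gt)
    e <- circ_err(ori[ok], gt[ok])
    errs <- c(errs, mean(e))
    hit15 <- c(hit15, mean(e < 15))
    invalid <- c(invalid, mean(is.na(ori)))
  }
  expect_true(all(errs < 10))      # circular MAE < 10 degrees
  expect_true(all(hit15 >= 0.95))  # >= 95% of valid pixels within 15 degrees
  expect_true(all(invalid < 0.05)) # < 5% invalid at 50% visibility
})
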