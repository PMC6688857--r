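test_that("paired-comparison tallies count percent chosen per appearance", {
  # stimulus winning every trial
  w <- matrix(c(0, 0, 2, 0), 2, 2)  # wins[1,2] = 2
  expect_equal(unname(tally_choices(paired_comparisons(w))), c(100, 0))

  # one trial each way: 50% each
  w2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(unname(tally_choices(paired_comparisons(w2))), c(50, 50))

  # 3-stimulus hand count at 2 trials/pair
  w3 <- rbind(c(0, 2, 2), c(0, 0, 2), c(0, 0, 0))
  expect_equal(unname(tally_choices(paired_comparisons(w3))), c(100, 50, 0))

  # complete balanced design: mean tally is exactly 50%
  set.seed(3)
  n <- 5; t <- 8
  wr <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    wr[i, j] <- rbinom(1, t, 0.5); wr[j, i] <- t - wr[i, j]
  }
  expect_equal(mean(tally_choices(paired_comparisons(wr))), 50)

  inc <- matrix(0, 3, 3); inc[1, 2] <- 1; inc[2, 1] <- 1
  expect_error(tally_choices(paired_comparisons(inc)), "incomplete")
})

test_that("correlation bins have closed 0.4 boundary and a <0.4 catch-all", {
  b <- bin_by_correlation(rep(0.95, 10), rep(TRUE, 10))
  expect_equal(b$percent_chosen[b$bin == "[0.9,1.0]"], 100)
  expect_true(all(is.na(b$percent_chosen[b$bin != "[0.9,1.0]"])))
  expect_equal(b$n_trials[b$bin == "[0.9,1.0]"], 10)

  b2 <- bin_by_correlation(c(0.39, 0.40), c(TRUE, FALSE))
  expect_equal(b2$n_trials[b2$bin == "<0.4"], 1)
  expect_equal(b2$n_trials[b2$bin == "[0.4,0.5)"], 1)
  expect_equal(b2$percent_chosen[b2$bin == "<0.4"], 100)
  expect_equal(b2$percent_chosen[b2$bin == "[0.4,0.5)"], 0)

  expect_error(bin_by_correlation(1.5, TRUE), "rho")
})

test_that("selection slope is plain OLS of percent chosen on noise percent", {
  w <- c(0, 25, 50, 75, 100)
  fit <- selection_slope(w, 100 - w)
  expect_equal(fit$slope, -1)
  expect_equal(fit$r_squared, 1)
  flat <- selection_slope(w, rep(50, 5))
  expect_equal(flat$slope, 0)
  expect_error(selection_slope(c(1, 1, 2), c(3, 4, 5)), "distinct")
})

test_that("Bradley-Terry scores solve the paired-comparison likelihood", {
  # symmetric data: all scores zero
  w <- matrix(c(0, 5, 5, 5, 0, 5, 5, 5, 0), 3, 3)
  f <- fit_latent_scores(paired_comparisons(w))
  expect_true(f$converged)
  expect_equal(unname(f$scores), rep(0, 3), tolerance = 1e-7)

  # two stimuli, 75/25 split: score difference log 3
  w2 <- matrix(0, 2, 2); w2[1, 2] <- 75; w2[2, 1] <- 25
  f2 <- fit_latent_scores(paired_comparisons(w2))
  expect_equal(unname(f2$scores[1] - f2$scores[2]), log(3), tolerance = 1e-6)
  expect_equal(sum(f2$scores), 0, tolerance = 1e-9)

  # permutation equivariance in stimulus labels
  set.seed(9)
  n <- 4
  wr <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    wr[i, j] <- rbinom(1, 40, plogis(i - j) * 0.8 + 0.1)
    wr[j, i] <- 40 - wr[i, j]
  }
  perm <- c(3, 1, 4, 2)
  f_a <- fit_latent_scores(paired_comparisons(wr))
  f_b <- fit_latent_scores(paired_comparisons(wr[perm, perm]))
  expect_equal(unname(f_b$scores), unname(f_a$scores[perm]), tolerance = 1e-6)

  # disconnected comparison graph is non-identifiable
  wd <- matrix(0, 4, 4)
  wd[1, 2] <- 3; wd[2, 1] <- 3; wd[3, 4] <- 3; wd[4, 3] <- 3
  expect_error(fit_latent_scores(paired_comparisons(wd)), "disconnected")
  # all-one-sided data likewise
  wo <- matrix(c(0, 0, 0, 5, 0, 0, 5, 5, 0), 3, 3)
  expect_error(fit_latent_scores(paired_comparisons(wo)), "non-identifiable")
})

test_that("gauge-figure profiles integrate slant/tilt settings correctly", {
  # slant 0 everywhere: flat profile
  flat <- reconstruct_profile(data.frame(probe = 1:20, slant = 0, tilt = 0))
  expect_true(all(flat$heights == 0))

  # constant 45-degree slant with tilt opposite the line: unit-slope ramp
  ramp <- reconstruct_profile(data.frame(probe = 1:20, slant = 45, tilt = 180))
  expect_equal(ramp$heights, 0:19, tolerance = 1e-9)

  # analytic ridge h(x) = exp(-x^2), exact normals: profile matches h
  xs <- seq(-2, 2, length.out = 20)
  hp <- -2 * xs * exp(-xs^2)
  settings <- data.frame(probe = 1:20,
                         slant = atan(abs(hp)) * 180 / pi,
                         tilt = ifelse(hp > 0, 180, 0))
  pr <- reconstruct_profile(settings, spacing = diff(xs)[1])
  truth <- exp(-xs^2) - exp(-4)
  expect_lt(max(abs(pr$heights - truth)), 0.02)  # < 2% of unit ridge height

  # repeats are averaged at the gradient stage
  two <- rbind(transform(settings, repeat_id = 1),
               transform(settings, slant = 0, repeat_id = 2))
  pr2 <- reconstruct_profile(two, spacing = diff(xs)[1])
  expect_equal(pr2$heights, pr$heights / 2, tolerance = 1e-9)

  expect_error(reconstruct_profile(data.frame(probe = 1:20, slant = 90,
                                              tilt = 0)), "unbounded")
  expect_error(reconstruct_profile(data.frame(probe = 1:19, slant = 0,
                                              tilt = 0)), "probes")
})

test_that("profile normalization scales observers to the grand mean", {
  p1 <- c(1, 2, 3, 4)
  single <- normalize_profiles(list(p1))
  expect_equal(single$mean_profile, p1)

  doubled <- normalize_profiles(list(p1, 2 * p1))
  expect_equal(mean(doubled$normalized[1, ]), mean(doubled$normalized[2, ]))
  expect_equal(doubled$normalized[1, ], doubled$normalized[2, ])

  # scale invariance of the output
  a <- normalize_profiles(list(p1, c(2, 1, 4, 3)))
  b <- normalize_profiles(list(5 * p1, c(2, 1, 4, 3)))
  expect_equal(a$normalized[2, ] / a$grand_mean,
               b$normalized[2, ] / b$grand_mean, tolerance = 1e-12)

  expect_error(normalize_profiles(list(c(-1, 1))), "zero-mean")
})
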