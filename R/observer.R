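# Synthetic observer: a latent-score choice model that stands in for
# human data, giving every analysis stage a generator with known
# ground truth.  The default coefficients are fixtures for testing the
# analysis pipeline, NOT estimates of human parameters.

#' Latent focus score of a stimulus
#'
#' Linear latent-score model combining the three stimulus properties
#' the analyses manipulate: the orientation-intensity covariation rho
#' (more covariation looks more focused), the convexity of the visible
#' surface regions (convex interpretations support contour attachment),
#' and defocus blur (blur reduces apparent focus).  Monotone increasing
#' in `rho` and `convex_fraction`, decreasing in `blur_level`.
#'
#' @param rho covariation score in `[-1, 1]`.
#' @param convex_fraction fraction of the percept that is convex, in
#'   `[0, 1]` (design value: 1 for convex level cuts, 0.5 for bistable,
#'   0.25 for rotated masks).
#' @param blur_level ordinal blur level (0 = none, 1 = weak, 2 =
#'   strong).
#' @param alpha,beta,gamma non-negative model coefficients (defaults 3,
#'   2, 1: fixture values, not fitted to human data).
#' @return Latent score(s), vectorized over the inputs.
#' @export
focus_score_model <- function(rho, convex_fraction, blur_level = 0,
                              alpha = 3, beta = 2, gamma = 1) {
  if (any(convex_fraction < 0 | convex_fraction > 1)) {
    stop_invalid("convex_fraction must be in [0, 1]")
  }
  if (any(rho < -1 | rho > 1)) stop_invalid("rho must be in [-1, 1]")
  alpha * rho + beta * convex_fraction - gamma * blur_level
}

#' Observer model
#'
#' @param scores named latent scores per stimulus.
#' @param tau decision noise (logistic scale), positive.
#' @param lapse lapse rate in `[0, 0.5)`: proportion of trials answered
#'   at random regardless of the stimuli.
#' @return An `observer_model` list.
#' @export
observer_model <- function(scores, tau = 1, lapse = 0) {
  if (tau <= 0) stop_invalid("decision noise tau must be positive")
  if (lapse < 0 || lapse >= 0.5) stop_invalid("lapse must be in [0, 0.5)")
  if (is.null(names(scores))) names(scores) <- as.character(seq_along(scores))
  structure(list(scores = scores, tau = tau, lapse = lapse),
            class = "observer_model")
}

#' Simulate paired-comparison choices
#'
#' Bradley-Terry (logistic) choice rule with a lapse floor:
#' `P(i over j) = (1 - 2 lapse) * plogis((s_i - s_j) / tau) + lapse`.
#' Seeded binomial draws fill the wins matrix for a complete
#' round-robin design.
#'
#' @param model an [observer_model].
#' @param trials_per_pair number of presentations of each unordered
#'   pair.
#' @param seed integer RNG seed.
#' @return A [paired_comparisons].
#' @export
simulate_choices <- function(model, trials_per_pair = 20, seed = 1) {
  stopifnot(inherits(model, "observer_model"))
  s <- model$scores
  n <- length(s)
  wins <- matrix(0L, n, n)
  with_seed(seed, {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      p <- (1 - 2 * model$lapse) * stats::plogis((s[i] - s[j]) / model$tau) +
        model$lapse
      wij <- stats::rbinom(1, trials_per_pair, p)
      wins[i, j] <- wij
      wins[j, i] <- trials_per_pair - wij
    }
  })
  paired_comparisons(wins, ids = names(s))
}

#' Simulate gauge-figure settings with angular noise
#'
#' Perturbs true probe attitudes with seeded Gaussian angular noise of
#' standard deviation `kappa` degrees on both slant and tilt (slant
#' clamped to `[0, 89.9]`).  `kappa = 0` returns the exact ground
#' truth.  Tilt follows the package convention (direction of the
#' projected surface normal, i.e. downhill).
#'
#' @param slant,tilt true per-probe attitudes in degrees (length =
#'   number of probes).
#' @param kappa angular noise standard deviation, degrees (>= 0).
#' @param repeats number of repeated settings per probe.
#' @param seed integer RNG seed.
#' @return Data frame with columns `probe`, `repeat_id`, `slant`,
#'   `tilt`, suitable for [reconstruct_profile].
#' @export
simulate_gauge_settings <- function(slant, tilt, kappa = 0, repeats = 1,
                                    seed = 1) {
  if (kappa < 0) stop_invalid("kappa must be non-negative")
  if (length(slant) != length(tilt)) stop_invalid("slant/tilt length mismatch")
  np <- length(slant)
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(repeats), function(r) {
      sl <- slant + if (kappa > 0) stats::rnorm(np, 0, kappa) else 0
      tl <- tilt + if (kappa > 0) stats::rnorm(np, 0, kappa) else 0
      data.frame(probe = seq_len(np), repeat_id = r,
                 slant = pmin(pmax(sl, 0), 89.9), tilt = wrap360(tl))
    }))
  })
  out
}
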