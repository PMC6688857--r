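# Paired-comparison tallies, correlation binning, selection-slope
# regression, Bradley-Terry latent scores, and gauge-figure relief
# reconstruction.

#' Paired-comparison data container
#'
#' @param wins square integer matrix; `wins[i, j]` counts the trials on
#'   which stimulus `i` was chosen over stimulus `j`.  Diagonal must be
#'   zero.
#' @param ids optional stimulus ids (defaults to rownames or 1..n).
#' @return An object of class `paired_comparisons`.
#' @export
paired_comparisons <- function(wins, ids = NULL) {
  wins <- as.matrix(wins)
  if (nrow(wins) != ncol(wins)) stop_invalid("wins matrix must be square")
  if (any(wins < 0)) stop_invalid("win counts must be non-negative")
  if (any(diag(wins) != 0)) stop_invalid("diagonal of wins must be zero")
  if (is.null(ids)) ids <- rownames(wins)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(wins)))
  dimnames(wins) <- list(ids, ids)
  structure(list(wins = wins, ids = ids), class = "paired_comparisons")
}

#' @export
print.paired_comparisons <- function(x, ...) {
  n <- length(x$ids)
  cat(sprintf("<paired_comparisons> %d stimuli, %d trials\n", n, sum(x$wins)))
  invisible(x)
}

#' Percent-chosen tally of a paired-comparison design
#'
#' For each stimulus, 100 times its wins divided by the number of
#' trials on which it appeared.  Requires a complete round-robin (every
#' pair presented at least once).  For any complete balanced design the
#' mean tally over stimuli is exactly 50%.
#'
#' @param d a [paired_comparisons].
#' @return Named numeric vector of percentages.
#' @export
tally_choices <- function(d) {
  stopifnot(inherits(d, "paired_comparisons"))
  w <- d$wins
  trials <- w + t(w)
  if (any(trials[upper.tri(trials)] < 1)) {
    stop_invalid("incomplete design: some pairs were never presented")
  }
  appearances <- rowSums(trials)
  stats::setNames(100 * rowSums(w) / appearances, d$ids)
}

#' Bin trial records by measured correlation
#'
#' Trials are sorted by the covariation rho of the presented stimulus
#' into bins `[0.9, 1.0]`, `[0.8, 0.9)`, ..., `[0.4, 0.5)` plus a
#' bottom bin collecting every rho below 0.4, and the percent of trials
#' chosen is computed per bin.  Empty bins are reported as `NA`
#' (missing), not zero.
#'
#' @param rho per-trial correlation values in `[-1, 1]`.
#' @param chosen logical per-trial: was this stimulus selected?
#' @return Data frame with `bin` (label), `lower`, `upper`, `n_trials`,
#'   `percent_chosen`.
#' @export
bin_by_correlation <- function(rho, chosen) {
  if (length(rho) != length(chosen)) stop_invalid("rho/chosen length mismatch")
  if (any(rho < -1 | rho > 1, na.rm = TRUE)) stop_invalid("rho must be in [-1, 1]")
  lowers <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, -1)
  uppers <- c(1.0, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  labels <- c("[0.9,1.0]", "[0.8,0.9)", "[0.7,0.8)", "[0.6,0.7)",
              "[0.5,0.6)", "[0.4,0.5)", "<0.4")
  idx <- vapply(rho, function(r) {
    if (r >= 0.9) 1L
    else if (r < 0.4) 7L
    else 7L - as.integer(floor((r - 0.4) / 0.1) + 1L)
  }, integer(1))
  n <- tabulate(idx, nbins = 7)
  pct <- rep(NA_real_, 7)
  for (b in which(n > 0)) pct[b] <- 100 * mean(chosen[idx == b])
  data.frame(bin = labels, lower = lowers, upper = uppers,
             n_trials = n, percent_chosen = pct)
}

#' Selection-percentage regression on noise level
#'
#' Ordinary least squares of percent-chosen on noise percentage; the
#' slope measures how many percentiles of selection likelihood are lost
#' per percentile of added ribbon noise.
#'
#' @param noise_pct noise levels, percent (at least 3 distinct values).
#' @param percent_chosen per-level percent-chosen.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
selection_slope <- function(noise_pct, percent_chosen) {
  if (length(unique(noise_pct)) < 3) {
    stop_invalid("need at least 3 distinct noise levels")
  }
  fit <- stats::lm(percent_chosen ~ noise_pct)
  tss <- sum((percent_chosen - mean(percent_chosen))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 0
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2)
}

#' Bradley-Terry latent scores from paired comparisons
#'
#' Maximum-likelihood latent scores under the logistic
#' (Bradley-Terry) choice model, identified by the zero-sum constraint
#' and fit by minorization-maximization iterations to a tolerance of
#' 1e-8 on the score change.  For two stimuli with a 75/25 split the
#' score difference is `log 3`.
#'
#' @param d a [paired_comparisons] whose comparison graph is connected
#'   and in which no stimulus wins or loses every trial.
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter iteration cap.
#' @return Object of class `bt_fit`: list with `scores` (named, zero
#'   sum), `iterations`, `converged`.
#' @export
fit_latent_scores <- function(d, tol = 1e-8, max_iter = 10000) {
  stopifnot(inherits(d, "paired_comparisons"))
  w <- d$wins
  n <- nrow(w)
  trials <- w + t(w)
  # connectivity of the comparison graph
  adj <- trials > 0
  seen <- logical(n); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  if (!all(seen)) stop_invalid("non-identifiable: comparison graph is disconnected")
  wi <- rowSums(w)
  if (any(wi == 0) || any(rowSums(t(w)) == 0)) {
    stop_invalid("non-identifiable: a stimulus won or lost every trial")
  }
  p <- rep(1, n)
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    denom <- vapply(seq_len(n), function(i) {
      sum(trials[i, -i] / (p[i] + p[-i]))
    }, numeric(1))
    p_new <- wi / denom
    p_new <- p_new / exp(mean(log(p_new)))   # geometric-mean normalization
    if (max(abs(log(p_new) - log(p))) < tol) {
      p <- p_new; converged <- TRUE; break
    }
    p <- p_new
  }
  structure(list(scores = stats::setNames(log(p), d$ids),
                 iterations = it, converged = converged),
            class = "bt_fit")
}

#' @export
print.bt_fit <- function(x, ...) {
  cat(sprintf("<bt_fit> Bradley-Terry scores (%d iterations%s)\n",
              x$iterations, if (x$converged) "" else ", NOT converged"))
  print(round(x$scores, 4))
  invisible(x)
}

#' @export
coef.bt_fit <- function(object, ...) object$scores

#' Reconstruct a relief profile from gauge-figure settings
#'
#' Each probe's along-line height gradient is derived from its
#' slant/tilt setting; repeats are averaged at the gradient stage
#' (integration is linear, so this equals averaging profiles while
#' tolerating missing repeats), and heights follow by trapezoidal
#' cumulative integration from zero.  Tilt here, as everywhere in the
#' package, is the direction of the image-projected surface normal
#' (downhill), so the along-line height gradient is
#' `-tan(slant) * cos(tilt - line_direction)`.
#'
#' @param settings data frame with columns `probe` (1..n_probes),
#'   `slant` (degrees, < 90), `tilt` (degrees); repeats are extra rows
#'   with the same probe index.
#' @param spacing probe spacing in distance units (default 1).
#' @param line_direction direction of the probe line in the image,
#'   degrees (default 0 = rightward).
#' @param n_probes number of probe positions (default 20).
#' @return Object of class `relief_profile`: list with `heights`
#'   (length `n_probes`), `gradient`, `spacing`.
#' @export
reconstruct_profile <- function(settings, spacing = 1, line_direction = 0,
                                n_probes = 20) {
  req <- c("probe", "slant", "tilt")
  if (!all(req %in% names(settings))) {
    stop_invalid("settings must have columns probe, slant, tilt")
  }
  if (any(settings$slant >= 90)) {
    stop_invalid("unbounded gradient: slant of 90 degrees")
  }
  if (!setequal(unique(settings$probe), seq_len(n_probes))) {
    stop_invalid("all ", n_probes, " probes must be present")
  }
  g_all <- -tan(deg2rad(settings$slant)) *
    cos(deg2rad(settings$tilt - line_direction))
  g <- as.numeric(tapply(g_all, factor(settings$probe, levels = seq_len(n_probes)),
                         mean))
  hts <- c(0, cumsum(spacing * (g[-1] + g[-length(g)]) / 2))
  structure(list(heights = hts, gradient = g, spacing = spacing),
            class = "relief_profile")
}

#' @export
print.relief_profile <- function(x, ...) {
  cat(sprintf("<relief_profile> %d probes, height range [%.3f, %.3f]\n",
              length(x$heights), min(x$heights), max(x$heights)))
  invisible(x)
}

#' Normalize relief profiles across observers
#'
#' Each observer's profile is multiplicatively scaled so its mean
#' height equals the grand mean over observers, then averaged with
#' per-point standard errors.  A zero-mean profile cannot be scaled and
#' raises an error.
#'
#' @param profiles list of `relief_profile`s (or numeric vectors of a
#'   common length).
#' @return List with `normalized` (matrix, observers in rows),
#'   `mean_profile`, `se_profile`, `grand_mean`.
#' @export
normalize_profiles <- function(profiles) {
  if (length(profiles) < 1) stop_invalid("need at least one profile")
  hm <- do.call(rbind, lapply(profiles, function(p) {
    if (inherits(p, "relief_profile")) p$heights else as.numeric(p)
  }))
  means <- rowMeans(hm)
  if (any(abs(means) < 1e-12)) {
    stop_invalid("cannot scale a zero-mean profile to the grand mean")
  }
  grand <- mean(means)
  norm <- hm * (grand / means)
  se <- if (nrow(norm) > 1) {
    apply(norm, 2, stats::sd) / sqrt(nrow(norm))
  } else rep(0, ncol(norm))
  list(normalized = norm, mean_profile = colMeans(norm), se_profile = se,
       grand_mean = grand)
}
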