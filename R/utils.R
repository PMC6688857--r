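# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All stochastic outputs in the package
# are pure functions of (arguments, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap angles in degrees into [0, 360).
wrap360 <- function(x) ((x %% 360) + 360) %% 360

# Wrap into [0, 180).
wrap180 <- function(x) ((x %% 180) + 180) %% 180

# Circular absolute difference in degrees, result in [0, 180].
circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# Separable Gaussian blur with a kernel truncated at 3 sigma and
# replicate-edge padding.  sigma = 0 returns the input unchanged.
gaussian_blur <- function(x, sigma) {
  if (sigma < 0) stop_invalid("smoothing sigma must be non-negative")
  if (sigma == 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- nrow(x); m <- ncol(x)
  # replicate-pad rows, convolve columns of the padded matrix, then rows
  pad_idx <- function(len) c(rep(1L, r), seq_len(len), rep(len, r))
  xp <- x[pad_idx(n), , drop = FALSE]
  tmp <- matrix(0, n, m)
  for (j in seq_len(m)) {
    tmp[, j] <- stats::filter(xp[, j], k, sides = 2)[(r + 1L):(r + n)]
  }
  tp <- tmp[, pad_idx(m), drop = FALSE]
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    out[i, ] <- stats::filter(tp[i, ], k, sides = 2)[(r + 1L):(r + m)]
  }
  out
}

# Matrix of radial frequencies (cycles/image) for an n x n DFT grid,
# unshifted (DC at [1,1]).
fft_radial_freq <- function(n) {
  f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  fr <- matrix(f, n, n)
  sqrt(fr^2 + t(fr)^2)
}
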