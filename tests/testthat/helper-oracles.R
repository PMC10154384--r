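# Independent brute-force oracles used across the test suite. These are kept
# deliberately naive and separate from the package's code paths.

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Kruskal-Wallis H from the definition (rank sums, no tie correction).
oracle_kw_H <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  12 / (N * (N + 1)) * sum(n * rbar^2) - 3 * (N + 1)
}

# Naive per-pulse amplitude: loop over raw samples, max minus baseline median.
oracle_pulse_amplitude <- function(time, proj, t0, i, pulse_on = 3,
                                   pulse_off = 4) {
  period <- pulse_on + pulse_off
  on0 <- t0 + (i - 1) * period
  mx <- -Inf
  base <- c()
  for (j in seq_along(time)) {
    if (time[j] >= on0 - 1e-9 && time[j] <= on0 + pulse_on + 1e-9)
      mx <- max(mx, proj[j])
    if (time[j] >= on0 - 1 - 1e-9 && time[j] < on0 - 1e-9)
      base <- c(base, proj[j])
  }
  max(0, mx - median(base))
}

# Analytic intensity-weighted centroid of a background-subtracted frame.
oracle_centroid <- function(frame, background) {
  w <- frame - background
  w[w < 0] <- 0
  xs <- matrix(0:(ncol(frame) - 1), nrow(frame), ncol(frame), byrow = TRUE)
  ys <- matrix(0:(nrow(frame) - 1), nrow(frame), ncol(frame))
  c(x = sum(w * xs) / sum(w), y = sum(w * ys) / sum(w))
}

# Exhaustive nearest-node matching: full distance matrix, one pass per
# centroid, ties to the smaller index.
oracle_nearest_assignment <- function(centroids_um, nodes_um, max_dist) {
  out <- rep(NA_integer_, nrow(centroids_um))
  for (i in seq_len(nrow(centroids_um))) {
    d <- sqrt(colSums((t(nodes_um) - centroids_um[i, ])^2))
    j <- which.min(d)
    if (d[j] <= max_dist) out[i] <- j
  }
  out
}

# Threshold crossing of a sampled profile by dense linear interpolation.
oracle_crossings <- function(z, p, thr) {
  zz <- seq(min(z), max(z), length.out = 200001)
  pp <- approx(z, p, xout = zz)$y
  above <- which(pp >= thr)
  c(bottom = zz[above[1]], top = zz[above[length(above)]])
}

# One noiseless rendered Gaussian spot on a constant background.
render_test_spot <- function(ny, nx, cx, cy, sigma, amplitude = 1000,
                             background = 100, noise_sd = 0) {
  xs <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  ys <- matrix(0:(ny - 1), ny, nx)
  img <- background + amplitude * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
  if (noise_sd > 0) img <- img + matrix(rnorm(ny * nx, sd = noise_sd), ny, nx)
  img
}

default_spec <- function() pillar_array_spec()

default_mask <- function(spec = default_spec(), n = 128, radius_um = 13) {
  disk_mask(n, n, radius_um = radius_um, pixel_size = spec$pixel_size)
}
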