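# Shared fixtures and independent oracles for the suite.

# Small chains keep the per-test simulation cost in milliseconds.
tiny_spec <- function(n = 12L, ...) {
  chain_spec(n_rowers = as.integer(n), ...)
}

# O(N^2) direct-sum spatial Fourier amplitudes: the independent oracle for
# fourier_coefficients (which uses fft).
fourier_oracle <- function(dphi, k_max) {
  n <- length(dphi)
  i <- seq_len(n) - 1
  vapply(seq_len(k_max), function(k) {
    re <- sum(dphi * cos(2 * pi * k * i / n))
    im <- sum(dphi * sin(2 * pi * k * i / n))
    2 * sqrt(re^2 + im^2) / n
  }, numeric(1))
}

# Exhaustive-summation oracle for the exact two-tailed binomial test:
# probability of all outcomes no more likely than the observed one.
binom_test_oracle <- function(k, n, p0 = 0.5) {
  dens <- vapply(0:n, function(x) stats::dbinom(x, n, p0), numeric(1))
  sum(dens[dens <= dens[k + 1] * (1 + 1e-7)])
}

# Pairwise 3-D bead distances on the periodic ring (minimum image along x).
min_bead_distance <- function(config, u) {
  pos <- bead_positions(config, u)
  n <- nrow(pos)
  dmin <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- minimum_image(pos[i, 1] - pos[j, 1], config$ring_length)
      dd <- sqrt(dx^2 + (pos[i, 2] - pos[j, 2])^2 + (pos[i, 3] - pos[j, 3])^2)
      dmin <- min(dmin, dd)
    }
  }
  dmin
}

# Wrap a plain phase-difference vector as a synthetic trajectory whose
# snapshots all hold the same profile: lets analysis-chain tests run without
# physics.  Phases are reconstructed by cumulative summation (ring-closing
# profiles only), then converted to (u, sigma) by inverting geometric_phase.
profile_to_trajectory <- function(dphi, n_cycles = 100, A = 30) {
  n <- length(dphi)
  phi <- (cumsum(c(0, dphi[-n]))) %% (2 * pi)
  sigma <- ifelse(phi < pi, 1L, -1L)
  u <- ifelse(sigma > 0, A * phi / pi - A / 2, A / 2 - A * (phi - pi) / pi)
  times_cycles <- seq(0, n_cycles, by = 0.1)
  cfg <- build_chain(chain_spec(n_rowers = n, amplitude = A))
  structure(list(
    times = times_cycles * 2, times_cycles = times_cycles,
    u = matrix(u, nrow = length(times_cycles), ncol = n, byrow = TRUE),
    sigma = matrix(sigma, nrow = length(times_cycles), ncol = n, byrow = TRUE),
    switch_times = numeric(0), switch_rower = integer(0),
    switch_sign = integer(0),
    config = cfg, seed = 0L, dt = 4e-3, dt_cycles = 2e-3, n_cycles = n_cycles
  ), class = "rower_trajectory")
}
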