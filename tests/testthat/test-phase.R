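test_that("geometric phase maps stroke position and direction to [0, 2pi)", {
  A <- 30
  expect_equal(geometric_phase(-15, 1, A), 0)
  expect_equal(geometric_phase(15, 1, A), pi)
  expect_equal(geometric_phase(15, -1, A), pi)    # continuous at the switch
  expect_equal(geometric_phase(-15, -1, A), 0)    # 2pi wraps to 0
  expect_equal(geometric_phase(0, 1, A), pi / 2)
  expect_equal(geometric_phase(0, -1, A), 3 * pi / 2)
  # overshoot past the switch point is clamped
  expect_equal(geometric_phase(15.4, 1, A), pi)
  # per-rower amplitude normalisation
  expect_equal(geometric_phase(5, 1, 20), geometric_phase(7.5, 1, 30))
})

test_that("phase advances monotonically by 2pi per period for a free rower", {
  traj <- simulate_chain(chain_spec(n_rowers = 1L, noise_level = 0),
                         n_cycles = 3, seed = 2,
                         sample_every_cycles = 0.01)
  phi <- geometric_phase(traj$u[, 1], traj$sigma[, 1], 30)
  unwrapped <- phi + 2 * pi * cumsum(c(0, diff(phi) < -pi))
  expect_true(all(diff(unwrapped) > 0))
  # advance per period: compare one full cycle apart (100 samples)
  expect_equal(unwrapped[301] - unwrapped[201], 2 * pi, tolerance = 0.01)
})

test_that("phase profile is the wrapped neighbour difference on the ring", {
  traj <- profile_to_trajectory(rep(0, 12))
  expect_equal(as.numeric(phase_profile(traj, 50)), rep(0, 12))

  # perfect metachronal wave with m wavelengths: constant dphi = 2 pi m / N
  n <- 12; m <- 2
  dphi <- rep(2 * pi * m / n, n)
  traj_w <- profile_to_trajectory(dphi)
  expect_equal(as.numeric(phase_profile(traj_w, 10)), dphi, tolerance = 1e-12)

  expect_error(phase_profile(traj, 1e6), "outside")
})

test_that("ring closure holds on every simulated snapshot", {
  traj <- simulate_chain(chain_spec(n_rowers = 10L), n_cycles = 5, seed = 3)
  for (tt in seq(0, 5, by = 0.5)) {
    s <- sum(phase_profile(traj, tt))
    expect_lt(min(abs(s - 2 * pi * (-10:10))), 1e-9)
  }
})

test_that("fourier coefficients match the direct-sum oracle", {
  set.seed(8)
  for (n in c(12, 30, 60)) {
    dphi <- rnorm(n)
    k_max <- max_fourier_mode(n)
    expect_equal(unname(fourier_coefficients(new_profile <- structure(
      dphi, class = "phase_profile"), k_max)),
      fourier_oracle(dphi, k_max), tolerance = 1e-12)
  }
  # constant profile has no structure
  expect_equal(unname(fourier_coefficients(rep(0.4, 60))), rep(0, 9),
               tolerance = 1e-12)
})

test_that("mode cutoff keeps features larger than three rowers", {
  expect_identical(max_fourier_mode(60), 9L)
  expect_identical(max_fourier_mode(30), 4L)
  k <- max_fourier_mode(60)
  expect_gt(60 / (2 * k), 3)
  expect_lte(60 / (2 * (k + 1)), 3)
})

test_that("square-wave profiles produce the analytic fundamental", {
  s <- 0.3
  sq1 <- make_fixture_profile("square", k = 1, amplitude = s, n_rowers = 60)
  ck <- fourier_coefficients(sq1)
  expect_equal(unname(ck[1]), 4 * s / pi, tolerance = 1e-3)
  expect_equal(which.max(ck), c(c1 = 1))

  sq3 <- make_fixture_profile("square", k = 3, amplitude = s, n_rowers = 60)
  ck3 <- fourier_coefficients(sq3)
  expect_equal(unname(which.max(ck3)), 3)
  expect_equal(unname(ck3[3]), 4 * s / pi, tolerance = 1e-2)
})

test_that("chevron detector applies the threshold rule", {
  # all coefficients just below threshold: no chevron
  det0 <- detect_chevrons(rep(0.14, 9))
  expect_identical(det0$chevron_count, 0L)
  expect_false(det0$above_threshold)

  # square wave s = 0.3 alternating every 10 of 60: three chevrons
  sq <- make_fixture_profile("square", k = 3, amplitude = 0.3, n_rowers = 60)
  det3 <- detect_chevrons(fourier_coefficients(sq))
  expect_identical(det3$chevron_count, 3L)
  expect_gt(det3$max_coefficient, 0.15)

  # flat profile: nothing
  fl <- make_fixture_profile("flat", amplitude = 0.2, n_rowers = 60)
  expect_identical(detect_chevrons(fourier_coefficients(fl))$chevron_count, 0L)

  # boundary: exactly at threshold counts as a chevron
  expect_identical(detect_chevrons(c(0.15, 0.01))$chevron_count, 1L)
})

test_that("run-level chevron count is the modal steady-state detection", {
  # constant synthetic profile: the count is the constructed k
  sq <- make_fixture_profile("square", k = 3, amplitude = 0.4, n_rowers = 60)
  traj <- profile_to_trajectory(as.numeric(sq), n_cycles = 100)
  expect_equal(as.integer(run_chevron_count(traj)), 3L)

  fl <- profile_to_trajectory(rep(0, 60), n_cycles = 100)
  expect_equal(as.integer(run_chevron_count(fl)), 0L)

  # window shorter than one cycle: no whole-cycle snapshot available
  frac <- profile_to_trajectory(rep(0, 60), n_cycles = 100.5)
  expect_error(run_chevron_count(frac, window = 0.001), "window")
})

test_that("modal count is stable against the analysis stride", {
  # seeded short stochastic runs: two different windows, same modal count
  agree <- 0L
  n_rep <- 8L
  for (r in seq_len(n_rep)) {
    traj <- simulate_chain(chain_spec(n_rowers = 12L), n_cycles = 40,
                           seed = 500 + r)
    c1 <- as.integer(run_chevron_count(traj, window = 0.05))
    c2 <- as.integer(run_chevron_count(traj, window = 0.10))
    if (c1 == c2) agree <- agree + 1L
  }
  expect_gte(agree, ceiling(0.95 * n_rep) - 1L)
})
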