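test_that("driving force follows the power-law trap", {
  # alpha = 1: constant magnitude k toward the vertex, independent of u
  f <- driving_force(c(-10, 0, 10), c(1, 1, 1), 30, 5, 1, 2.5)
  expect_equal(f, rep(5, 3))
  expect_equal(driving_force(0, -1, 30, 5, 1, 2.5), -5)

  # alpha = 0.5 closed form at the stroke start
  f0 <- driving_force(-15, 1, 30, 7, 0.5, 2.5)
  expect_equal(f0, 0.5 * 7 * (30 + 2.5)^(-0.5))

  # magnitude strictly increases approaching the switch point for alpha < 1
  us <- seq(-15, 14.9, by = 0.3)
  mags <- abs(driving_force(us, rep(1, length(us)), 30, 7, 0.5, 2.5))
  expect_true(all(diff(mags) > 0))
})

test_that("geometric switch fires exactly at the threshold crossing", {
  expect_equal(switch_update(0, 1, 30), 1)
  expect_equal(switch_update(15, 1, 30), -1)
  expect_equal(switch_update(15, -1, 30), -1)   # already heading away
  expect_equal(switch_update(-15, -1, 30), 1)
  expect_equal(switch_update(14.99, 1, 30), 1)
})

test_that("trap calibration matches the quadrature oracle and simulation", {
  gamma <- 6 * pi
  # alpha = 1: constant-force stroke, k = 2 gamma A / T
  expect_equal(calibrate_trap_strength(gamma, 30, 2.5, 1, 2), 2 * gamma * 30 / 2)

  # closed form vs independent numeric quadrature, alpha = 0.5 defaults
  k_cf <- calibrate_trap_strength(gamma, 30, 2.5, 0.5, 2)
  half_time <- function(k, alpha) {
    gamma * stats::integrate(function(r) r^(1 - alpha), 2.5, 32.5,
                             rel.tol = 1e-12)$value / (alpha * k)
  }
  k_quad <- uniroot(function(k) 2 * half_time(k, 0.5) - 2,
                    c(k_cf / 2, k_cf * 2), tol = 1e-10)$root
  expect_lt(abs(k_cf - k_quad) / k_quad, 1e-8)

  # and for other exponents
  for (alpha in c(0.3, 0.75)) {
    k_a <- calibrate_trap_strength(gamma, 30, 2.5, alpha, 2)
    expect_lt(abs(2 * half_time(k_a, alpha) - 2), 1e-8)
  }

  # simulated noise-free rower beats at the target period within one step
  traj <- simulate_chain(chain_spec(n_rowers = 1L, noise_level = 0),
                         n_cycles = 40, seed = 1)
  expect_lt(abs(measure_period(traj) - 2), traj$dt)
})

test_that("thermal step has covariance 2 kBT M dt", {
  expect_equal(thermal_step(diag(3) * 0.2, 0, 0.01), rep(0, 3))

  # diagonal M: independent components with the stated variance
  set.seed(42)
  M <- diag(c(1, 2, 4)) * 0.05
  kBT <- 0.7; dt <- 4e-3
  draws <- t(replicate(4e4, thermal_step(M, kBT, dt)))
  expect_equal(unname(apply(draws, 2, var)), 2 * kBT * diag(M) * dt,
               tolerance = 0.03)
  expect_lt(max(abs(cor(draws)[upper.tri(diag(3))])), 0.03)

  # dense SPD 5x5 against the Monte-Carlo oracle
  set.seed(43)
  A <- matrix(rnorm(25), 5)
  M5 <- crossprod(A) / 10 + diag(5) * 0.1
  draws5 <- t(replicate(1e5, thermal_step(M5, kBT, dt)))
  emp <- cov(draws5)
  expect_lt(max(abs(emp - 2 * kBT * M5 * dt)) / max(abs(2 * kBT * M5 * dt)),
            0.03)
})

test_that("coupled 60-rower noise covariance matches 2 kBT M dt", {
  cfg <- build_chain(chain_spec())
  M <- unclass(projected_mobility(cfg, rep(0, 60)))
  kBT <- noise_energy(cfg); dt <- 4e-3
  set.seed(44)
  draws <- t(replicate(2e4, thermal_step(M, kBT, dt)))
  emp <- cov(draws)
  expect_lt(max(abs(emp - 2 * kBT * M * dt)) / max(2 * kBT * M * dt), 0.03)
})

test_that("compiled integrator matches the pure-R reference stepper", {
  spec <- chain_spec(n_rowers = 6L, noise_level = 0)
  cfg <- build_chain(spec)
  set.seed(9)
  st <- initial_state(cfg)
  n_steps <- 500L
  dt <- 2e-3 * 2
  stR <- st
  for (i in seq_len(n_steps)) stR <- step_chain(stR, cfg, dt)
  traj <- simulate_chain(cfg, n_cycles = n_steps * 2e-3, dt_cycles = 2e-3,
                         seed = 1, initial = st,
                         sample_every_cycles = n_steps * 2e-3)
  last <- nrow(traj$u)
  expect_equal(traj$u[last, ], stR$u, tolerance = 1e-10)
  expect_equal(as.integer(traj$sigma[last, ]), as.integer(stR$sigma))
})

test_that("noise-free single rower follows the 1-D quadrature solution", {
  # position at time t on the first upstroke, from the exact quadrature:
  # r(t) solves r0^(3/2) - r^(3/2) = 3 alpha k t / (2 gamma) for alpha = 1/2
  spec <- chain_spec(n_rowers = 1L, noise_level = 0)
  cfg <- build_chain(spec)
  k <- cfg$trap_strength_i[1]; gamma <- cfg$drag
  traj <- simulate_chain(cfg, n_cycles = 0.4, dt_cycles = 2e-3, seed = 1,
                         initial = list(u = -15, sigma = 1L),
                         sample_every_cycles = 0.02)
  r0 <- 32.5
  mob <- 1 / gamma
  exact_u <- function(t) {
    r <- (r0^1.5 - 1.5 * 0.5 * k * mob * t)^(2 / 3)
    17.5 - r
  }
  sel <- traj$times <= 0.75   # stay within the first half stroke
  expect_equal(traj$u[sel, 1], vapply(traj$times[sel], exact_u, numeric(1)),
               tolerance = 1e-4)
})

test_that("deterministic trajectories converge under step halving", {
  spec <- chain_spec(n_rowers = 4L, noise_level = 0)
  cfg <- build_chain(spec)
  set.seed(14)
  st <- initial_state(cfg)
  final_u <- function(dtc) {
    traj <- simulate_chain(cfg, n_cycles = 2, dt_cycles = dtc, seed = 1,
                           initial = st, sample_every_cycles = 2)
    traj$u[nrow(traj$u), ]
  }
  ref <- final_u(6.25e-5)
  err <- vapply(c(2e-3, 1e-3, 5e-4), function(d) max(abs(final_u(d) - ref)),
                numeric(1))
  expect_true(all(diff(err) < 0))          # errors shrink with dt
  expect_gt(err[1] / err[2], 1.8)          # at least first-order decay
})

test_that("simulation contracts: determinism, symmetry, switch counts", {
  spec <- chain_spec(n_rowers = 8L)
  t1 <- simulate_chain(spec, n_cycles = 3, seed = 77)
  t2 <- simulate_chain(spec, n_cycles = 3, seed = 77)
  expect_identical(t1$u, t2$u)
  expect_identical(t1$switch_times, t2$switch_times)

  # zero noise + identical initial conditions: permutation symmetry for all time
  spec0 <- chain_spec(n_rowers = 8L, noise_level = 0)
  init <- list(u = rep(3.2, 8), sigma = rep(1L, 8))
  t3 <- simulate_chain(spec0, n_cycles = 5, seed = 1, initial = init)
  expect_true(all(apply(t3$u, 1, function(x) max(x) - min(x)) < 1e-12))

  # noise-free runs switch exactly twice per rower per cycle
  t4 <- simulate_chain(spec0, n_cycles = 10, seed = 5)
  n_sw <- table(t4$switch_rower)
  expect_true(all(abs(n_sw - 20) <= 1))    # edge cycles may clip one switch
})

test_that("far-separated rowers evolve like isolated ones", {
  # two rowers on a huge ring: coupling ~ h^2/r^3 is negligible
  spec2 <- chain_spec(n_rowers = 2L, spacing = 5000, noise_level = 0)
  spec1 <- chain_spec(n_rowers = 1L, noise_level = 0)
  init2 <- list(u = c(-3, 8), sigma = c(1L, -1L))
  t2 <- simulate_chain(spec2, n_cycles = 3, seed = 1, initial = init2)
  t1a <- simulate_chain(spec1, n_cycles = 3, seed = 1,
                        initial = list(u = -3, sigma = 1L))
  t1b <- simulate_chain(spec1, n_cycles = 3, seed = 1,
                        initial = list(u = 8, sigma = -1L))
  expect_equal(t2$u[, 1], t1a$u[, 1], tolerance = 1e-6)
  expect_equal(t2$u[, 2], t1b$u[, 1], tolerance = 1e-6)
})

test_that("noise interpretation: kBT is xi times the half-stroke energy drop", {
  cfg <- build_chain(chain_spec())
  k <- cfg$trap_strength_i[1]
  expect_equal(noise_energy(cfg),
               3.7e-5 * k * (32.5^0.5 - 2.5^0.5))
  cfg0 <- build_chain(chain_spec(noise_level = 0))
  expect_equal(noise_energy(cfg0), 0)
})

test_that("a uniform chain with weak noise settles into phase lock", {
  spec <- chain_spec(n_rowers = 15L)   # default (small) noise level
  traj <- simulate_chain(spec, n_cycles = 400, seed = 6)
  d300 <- as.numeric(phase_profile(traj, 300))
  d400 <- as.numeric(phase_profile(traj, 400))
  drift_per_cycle <- max(abs(wrap_angle(d400 - d300))) / 100
  expect_lt(drift_per_cycle, 0.01 * 2 * pi)
})
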