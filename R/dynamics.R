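#' Trap driving force along the track
#'
#' The rower is driven by an attractive power-law potential
#' \eqn{k |x - x_v|^\alpha} whose vertex sits a distance
#' \code{switch_offset} beyond the switch point: vertex at
#' \eqn{v = \sigma (A/2 + x_s)}.  The force magnitude is
#' \eqn{\alpha k r^{\alpha - 1}} at distance r from the vertex, directed
#' toward it.
#'
#' @param u track coordinate relative to the track centre (vectorised).
#' @param sigma trap orientation, +1 or -1 (vectorised).
#' @param amplitude beat amplitude A.
#' @param trap_strength trap strength k.
#' @param force_exponent exponent alpha in (0, 1].
#' @param switch_offset vertex offset x_s beyond the switch point.
#' @return signed force along the track.
#' @export
driving_force <- function(u, sigma, amplitude, trap_strength,
                          force_exponent, switch_offset) {
  v <- sigma * (amplitude / 2 + switch_offset)
  r <- abs(v - u)
  if (any(r == 0))
    stop("bead at the trap vertex: force undefined (unreachable when the switch fires at x_s)")
  force_exponent * trap_strength * r^(force_exponent - 1) * sign(v - u)
}

#' Geometric switch update
#'
#' The trap flips when the bead crosses the switch point a distance
#' \code{switch_offset} short of the vertex, i.e. when \eqn{\sigma u \ge A/2}.
#'
#' @param u track coordinate (vectorised).
#' @param sigma current trap orientation (vectorised).
#' @param amplitude beat amplitude A.
#' @return updated orientation vector.
#' @export
switch_update <- function(u, sigma, amplitude) {
  ifelse(sigma * u >= amplitude / 2, -sigma, sigma)
}

#' Calibrate the trap strength to a target beat period
#'
#' For the deterministic isolated rower, the half-stroke time follows from the
#' overdamped equation \eqn{\gamma \dot u = \alpha k r^{\alpha-1}} by
#' quadrature over the vertex distance r from \eqn{A + x_s} down to
#' \eqn{x_s}:
#' \deqn{T = \frac{2\gamma}{\alpha (2-\alpha) k}
#'       \left[(A + x_s)^{2-\alpha} - x_s^{2-\alpha}\right].}
#' Inverting gives the trap strength; for \eqn{\alpha = 1/2} this reduces to
#' \eqn{k = (8\gamma / 3T)[(A + x_s)^{3/2} - x_s^{3/2}]}.
#'
#' @param drag bead drag gamma = 6 pi eta a.
#' @param amplitude beat amplitude A.
#' @param switch_offset vertex offset x_s.
#' @param force_exponent exponent alpha in (0, 1].
#' @param target_period desired period T.
#' @return trap strength k.
#' @export
calibrate_trap_strength <- function(drag, amplitude, switch_offset,
                                    force_exponent, target_period) {
  stopifnot(drag > 0, amplitude > 0, switch_offset > 0, target_period > 0,
            force_exponent > 0, force_exponent <= 1)
  a2 <- 2 - force_exponent
  2 * drag * ((amplitude + switch_offset)^a2 - switch_offset^a2) /
    (force_exponent * a2 * target_period)
}

#' Thermal energy implied by the dimensionless noise level
#'
#' The noise level xi is interpreted as the ratio of thermal energy to the
#' driving-potential drop over one half stroke of an unmodified rower,
#' \eqn{k_B T = \xi \, k [(A + x_s)^\alpha - x_s^\alpha]}.  Kept behind this
#' single conversion so an alternative convention touches one line.
#'
#' @param config a \code{chain_config}.
#' @return thermal energy kBT in simulation units.
#' @export
noise_energy <- function(config) {
  spec <- config$spec
  gamma <- config$drag
  k_base <- calibrate_trap_strength(gamma, spec$amplitude, spec$switch_offset,
                                    spec$force_exponent, spec$target_period)
  dE <- k_base * ((spec$amplitude + spec$switch_offset)^spec$force_exponent -
                    spec$switch_offset^spec$force_exponent)
  spec$noise_level * dE
}

#' Correlated Brownian displacement
#'
#' Draws one Gaussian displacement vector with mean zero and covariance
#' \eqn{2 k_B T M \, dt}, via the Cholesky factor of the mobility matrix
#' (Ermak-McCammon random step; the mobility-divergence drift vanishes here
#' because beads ride fixed-height 1-D tracks and the configuration dependence
#' of the projected mobility is a far-field correction).
#'
#' @param M SPD mobility matrix.
#' @param kBT thermal energy.
#' @param dt time step.
#' @return displacement vector of length nrow(M).
#' @export
thermal_step <- function(M, kBT, dt) {
  stopifnot(dt > 0, kBT >= 0)
  n <- nrow(M)
  if (kBT == 0) return(numeric(n))
  L <- t(chol(M))   # lower factor; chol() errors on non-SPD input
  sqrt(2 * kBT * dt) * drop(L %*% stats::rnorm(n))
}

#' One integration step of the coupled chain (reference implementation)
#'
#' Pure-R stepper mirroring the compiled integrator, used as its cross-check:
#' a Heun (predictor-corrector) drift stage with the mobility held at the
#' start-of-step configuration, the Ermak-McCammon random displacement, then
#' the geometric switch with the crossing located inside the step by linear
#' interpolation and the reversed stroke restarted from the switch point for
#' the remaining step fraction.  (Plain Euler with step-resolution switching
#' biases the beat period by several time steps per cycle.)
#'
#' @param state list with components \code{u} and \code{sigma}.
#' @param config a \code{chain_config}.
#' @param dt time step in seconds.
#' @param kBT thermal energy (0 disables noise).
#' @return updated state list.
#' @export
step_chain <- function(state, config, dt, kBT = 0) {
  spec <- config$spec
  A_i <- config$amplitude_i
  x_s <- config$switch_offset_i
  sig <- state$sigma
  M <- unclass(projected_mobility(config, state$u, check_spd = FALSE))
  F1 <- driving_force(state$u, sig, A_i, config$trap_strength_i,
                      spec$force_exponent, x_s)
  u_pred <- state$u + drop(M %*% F1) * dt
  # corrector force; freeze it when the predictor lands past the vertex side
  past <- (sig * (A_i / 2 + x_s) - u_pred) * sig <= 0
  u_eval <- ifelse(past, state$u, u_pred)
  F2 <- driving_force(u_eval, sig, A_i, config$trap_strength_i,
                      spec$force_exponent, x_s)
  u_new <- state$u + drop(M %*% ((F1 + F2) / 2)) * dt +
    thermal_step(M, kBT, dt)
  if (any(abs(u_new) > A_i / 2 + x_s))
    stop("bead stepped past the trap vertex: reduce dt")
  crossed <- sig * u_new >= A_i / 2
  if (any(crossed)) {
    self_mob <- 1 / (6 * pi * spec$viscosity * spec$bead_radius)
    for (i in which(crossed)) {
      u_sw <- sig[i] * A_i[i] / 2
      du <- u_new[i] - state$u[i]
      theta <- if (du != 0) min(max((u_sw - state$u[i]) / du, 0), 1) else 1
      sig[i] <- -sig[i]
      f_new <- driving_force(u_sw, sig[i], A_i[i], config$trap_strength_i[i],
                             spec$force_exponent, x_s[i])
      u_new[i] <- u_sw + self_mob * f_new * (1 - theta) * dt
    }
  }
  list(u = u_new, sigma = sig)
}

#' Draw the random initial state of a chain
#'
#' Starting positions are uniform on (-A_i/2, A_i/2) per rower and the trap
#' orientation is a fair coin, drawn from R's current RNG stream.
#'
#' @param config a \code{chain_config}.
#' @return list with components \code{u} and \code{sigma}.
#' @export
initial_state <- function(config) {
  n <- config$spec$n_rowers
  list(u = stats::runif(n, -config$amplitude_i / 2, config$amplitude_i / 2),
       sigma = ifelse(stats::runif(n) < 0.5, -1L, 1L))
}

#' Simulate a rower chain
#'
#' Integrates the overdamped Langevin dynamics of the full chain with the
#' compiled Euler-Maruyama core: track-projected Blake mobility recomputed
#' every step (optionally cached at track centres), power-law driving forces,
#' correlated thermal noise with covariance \eqn{2 k_B T M dt}, and the
#' geometric switch applied after each step.  Fully reproducible from
#' \code{(spec, seed)}.
#'
#' @param spec a [chain_spec()] (or a prebuilt \code{chain_config}).
#' @param n_cycles simulation length in beat cycles (default 2000).
#' @param dt_cycles time step in cycles (default 2e-3).
#' @param seed integer RNG seed for initial conditions and noise.
#' @param sample_every_cycles sampling stride for stored states, in cycles
#'   (default 0.1).
#' @param initial optional list(u, sigma) overriding the random initial state.
#' @param decouple_groups if TRUE, zero the mobility coupling between rowers
#'   in different groups (diagnostic limit of infinitely separated groups).
#' @param cache_mobility if TRUE, evaluate the mobility once at the track
#'   centres instead of every step (documented speed option, off by default).
#' @return object of class \code{rower_trajectory}: list with \code{times}
#'   (seconds), \code{times_cycles}, \code{u} (samples x N), \code{sigma}
#'   (samples x N), \code{switch_times}/\code{switch_rower}/\code{switch_sign}
#'   (event log), \code{config}, \code{seed}, \code{dt}.
#' @export
simulate_chain <- function(spec, n_cycles = 2000, dt_cycles = 2e-3,
                           seed = 1L, sample_every_cycles = 0.1,
                           initial = NULL, decouple_groups = FALSE,
                           cache_mobility = FALSE) {
  config <- if (inherits(spec, "chain_config")) spec else build_chain(spec)
  spec <- config$spec
  stopifnot(n_cycles > 0, dt_cycles > 0, sample_every_cycles >= dt_cycles)

  dt <- dt_cycles * spec$target_period
  n_steps <- round(n_cycles / dt_cycles)
  sample_every <- max(1L, round(sample_every_cycles / dt_cycles))

  set.seed(seed)
  st <- if (is.null(initial)) initial_state(config) else initial
  stopifnot(length(st$u) == spec$n_rowers,
            all(st$sigma %in% c(-1L, 1L)))

  res <- rower_simulate_cpp(
    config$track_x, config$ring_length, config$amplitude_i,
    config$trap_strength_i, config$switch_offset_i[1], spec$force_exponent,
    spec$bead_radius, spec$height, spec$viscosity, spec$tilt_angle,
    noise_energy(config), dt, as.integer(n_steps), as.integer(sample_every),
    st$u, as.integer(st$sigma), as.integer(config$group_id),
    isTRUE(decouple_groups), isTRUE(cache_mobility))

  structure(list(
    times = res$times,
    times_cycles = res$times / spec$target_period,
    u = res$u, sigma = res$sigma,
    switch_times = res$switch_times,
    switch_rower = res$switch_rower,
    switch_sign = res$switch_sign,
    config = config, seed = seed, dt = dt, dt_cycles = dt_cycles,
    n_cycles = n_cycles
  ), class = "rower_trajectory")
}

#' Measure the mean beat period of one rower from its switch events
#'
#' Averages the intervals between successive switches to the same trap
#' orientation (one full cycle each).
#'
#' @param traj a \code{rower_trajectory}.
#' @param rower 1-based rower index.
#' @param sign which orientation flip delimits a cycle (+1: upstroke start).
#' @return mean period in seconds (NA if fewer than two matching events).
#' @export
measure_period <- function(traj, rower = 1L, sign = 1L) {
  sel <- traj$switch_rower == rower & traj$switch_sign == sign
  tt <- traj$switch_times[sel]
  if (length(tt) < 2) return(NA_real_)
  mean(diff(tt))
}

#' @export
print.rower_trajectory <- function(x, ...) {
  cat(sprintf("rower trajectory: N = %d, %g cycles, dt = %g cycles, seed = %d\n",
              x$config$spec$n_rowers, x$n_cycles, x$dt_cycles, x$seed))
  invisible(x)
}
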