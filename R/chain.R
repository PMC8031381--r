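#' Specify a rower chain
#'
#' A rower is a minimal model of a motile cilium: a bead of radius \code{a}
#' driven along a fixed 1-D track by an attractive power-law trap whose centre
#' flips when the bead crosses a geometric switch point.  A chain is \code{N}
#' such rowers on parallel tracks above a plane no-slip wall, wrapped by a
#' periodic boundary along \code{x}.
#'
#' All lengths are in units of the bead radius (\code{bead_radius = 1} by
#' default, nominally 1 micron), times in seconds, viscosity in arbitrary
#' consistent units (the drag \eqn{\gamma = 6\pi\eta a} sets the time scale
#' jointly with the trap strength, which is calibrated to \code{target_period}).
#'
#' Exactly one of three control mechanisms may be applied on top of the uniform
#' chain:
#' \describe{
#'   \item{\code{"spacing"}}{every \code{group_size} rowers the gap is enlarged
#'     by \code{d_X}, splitting the chain into equal groups with reduced
#'     inter-group coupling (only \code{d_X >= 0} is supported).}
#'   \item{\code{"amplitude"}}{every \code{group_size}-th rower beats with
#'     amplitude \code{A + A_X}; its trap strength is recalibrated so its
#'     single-rower period stays \code{target_period}.}
#'   \item{\code{"frequency"}}{every \code{group_size}-th rower has its trap
#'     strength scaled by \code{f_X}, detuning its intrinsic frequency while
#'     the amplitude is unchanged.}
#' }
#'
#' @param n_rowers integer, number of rowers N (default 60).
#' @param bead_radius bead radius a (length unit; default 1).
#' @param spacing nominal track separation d along x (default 7).
#' @param height track height h above the wall (default 3); must exceed
#'   \code{bead_radius} so the bead clears the wall.
#' @param amplitude beat amplitude A (full stroke length; default 30).
#' @param tilt_angle track tilt from the x axis, in radians, within the plane
#'   z = h (default \code{pi/4}).
#' @param switch_offset distance x_s between switch point and trap vertex
#'   (default 2.5).
#' @param force_exponent trap potential exponent alpha in (0, 1] (default 0.5,
#'   i.e. an attractive square-root potential).
#' @param target_period single-rower beat period T the trap strength is
#'   calibrated to, in seconds (default 2).
#' @param noise_level dimensionless noise xi: thermal energy as a fraction of
#'   the driving-potential drop per half stroke (default 3.7e-5).
#' @param viscosity dynamic viscosity eta (default 1).
#' @param mechanism one of \code{"none"}, \code{"spacing"}, \code{"amplitude"},
#'   \code{"frequency"}.
#' @param group_size group size N_g; N must be divisible by N_g when a
#'   mechanism is active (default 10).
#' @param d_X extra gap inserted every N_g rowers (spacing mechanism; >= 0).
#' @param A_X signed amplitude change of every N_g-th rower (amplitude
#'   mechanism; \code{amplitude + A_X} must stay positive).
#' @param f_X trap-strength scale factor of every N_g-th rower (frequency
#'   mechanism; > 0).
#' @return an object of class \code{chain_spec}.
#' @seealso [build_chain()]
#' @export
chain_spec <- function(n_rowers = 60L,
                       bead_radius = 1,
                       spacing = 7,
                       height = 3,
                       amplitude = 30,
                       tilt_angle = pi / 4,
                       switch_offset = 2.5,
                       force_exponent = 0.5,
                       target_period = 2,
                       noise_level = 3.7e-5,
                       viscosity = 1,
                       mechanism = c("none", "spacing", "amplitude", "frequency"),
                       group_size = 10L,
                       d_X = 0,
                       A_X = 0,
                       f_X = 1) {
  mechanism <- match.arg(mechanism)
  n_rowers <- as.integer(n_rowers)
  group_size <- as.integer(group_size)

  stopifnot(n_rowers > 0L, bead_radius > 0, spacing > 0, amplitude > 0,
            switch_offset > 0, target_period > 0, viscosity > 0,
            noise_level >= 0)
  if (height <= bead_radius)
    stop("height must exceed bead_radius: the bead must clear the wall")
  if (force_exponent <= 0 || force_exponent > 1)
    stop("force_exponent must lie in (0, 1]")
  if (mechanism != "none") {
    if (group_size <= 0L || n_rowers %% group_size != 0L)
      stop("n_rowers must be divisible by group_size when a mechanism is active")
  }
  if (mechanism == "spacing" && d_X < 0)
    stop("only reduced coupling (d_X >= 0) is supported")
  if (mechanism == "amplitude" && amplitude + A_X <= 0)
    stop("amplitude + A_X must be positive")
  if (mechanism == "frequency" && f_X <= 0)
    stop("f_X must be positive")

  structure(list(
    n_rowers = n_rowers, bead_radius = bead_radius, spacing = spacing,
    height = height, amplitude = amplitude, tilt_angle = tilt_angle,
    switch_offset = switch_offset, force_exponent = force_exponent,
    target_period = target_period, noise_level = noise_level,
    viscosity = viscosity, mechanism = mechanism, group_size = group_size,
    d_X = d_X, A_X = A_X, f_X = f_X
  ), class = "chain_spec")
}

#' Build the chain configuration from a specification
#'
#' Lays the tracks out along x (rower 0 at the origin), applies the selected
#' control mechanism, and calibrates per-rower trap strengths.  Tracks are
#' parallel lines in the plane z = height, all tilted by \code{tilt_angle}
#' from x; the ring is closed periodically with total length
#' \code{ring_length}.
#'
#' @param spec a [chain_spec()].
#' @return an object of class \code{chain_config} with components
#'   \code{track_x} (track centre x-coordinates), \code{track_direction}
#'   (shared unit 3-vector), \code{ring_length}, \code{amplitude_i},
#'   \code{trap_strength_i}, \code{switch_offset_i}, \code{group_id}
#'   (1-based group index per rower), \code{modified} (logical, rowers touched
#'   by the mechanism), and the originating \code{spec}.
#' @export
build_chain <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  n <- spec$n_rowers
  idx <- seq_len(n) - 1L
  gamma <- 6 * pi * spec$viscosity * spec$bead_radius

  k_base <- calibrate_trap_strength(gamma, spec$amplitude, spec$switch_offset,
                                    spec$force_exponent, spec$target_period)

  track_x <- idx * spec$spacing
  ring_length <- n * spec$spacing
  A_i <- rep(spec$amplitude, n)
  k_i <- rep(k_base, n)
  modified <- rep(FALSE, n)

  if (spec$mechanism == "spacing") {
    track_x <- idx * spec$spacing + (idx %/% spec$group_size) * spec$d_X
    ring_length <- n * spec$spacing + (n %/% spec$group_size) * spec$d_X
  } else if (spec$mechanism == "amplitude") {
    modified <- idx %% spec$group_size == 0L
    A_i[modified] <- spec$amplitude + spec$A_X
    # the beat frequency is maintained: recalibrate the trap of modified rowers
    k_i[modified] <- calibrate_trap_strength(gamma, spec$amplitude + spec$A_X,
                                             spec$switch_offset,
                                             spec$force_exponent,
                                             spec$target_period)
  } else if (spec$mechanism == "frequency") {
    modified <- idx %% spec$group_size == 0L
    k_i[modified] <- spec$f_X * k_base
  }

  group_id <- if (spec$mechanism == "none") rep(1L, n) else
    as.integer(idx %/% spec$group_size) + 1L

  structure(list(
    track_x = track_x,
    track_direction = c(cos(spec$tilt_angle), sin(spec$tilt_angle), 0),
    ring_length = ring_length,
    amplitude_i = A_i,
    trap_strength_i = k_i,
    switch_offset_i = rep(spec$switch_offset, n),
    group_id = group_id,
    modified = modified,
    drag = gamma,
    spec = spec
  ), class = "chain_config")
}

#' Minimum-image separation on a periodic ring
#'
#' Shifts a separation \code{dx} by multiples of the ring length \code{L} into
#' the half-open interval (-L/2, L/2].  Used for the x-separation between
#' tracks; y and z separations are taken as-is (the ring topology is 1-D and
#' the wall-screened coupling decays fast enough that higher images are
#' negligible).
#'
#' @param dx separation (vectorised).
#' @param L ring length, > 0.
#' @return wrapped separation in (-L/2, L/2].
#' @export
minimum_image <- function(dx, L) {
  stopifnot(L > 0)
  out <- dx - L * round(dx / L)
  out[out <= -L / 2] <- out[out <= -L / 2] + L
  out
}

#' Bead positions for a chain state
#'
#' @param config a \code{chain_config}.
#' @param u numeric vector of track coordinates (relative to track centres).
#' @return an N x 3 matrix of bead positions.
#' @export
bead_positions <- function(config, u) {
  stopifnot(length(u) == config$spec$n_rowers)
  t_hat <- config$track_direction
  cbind(config$track_x + u * t_hat[1],
        u * t_hat[2],
        config$spec$height + u * t_hat[3])
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("rower chain spec: N = %d, d = %g, h = %g, A = %g, mechanism = %s\n",
              x$n_rowers, x$spacing, x$height, x$amplitude, x$mechanism))
  if (x$mechanism != "none")
    cat(sprintf("  group_size = %d, d_X = %g, A_X = %g, f_X = %g\n",
                x$group_size, x$d_X, x$A_X, x$f_X))
  invisible(x)
}

#' @export
print.chain_config <- function(x, ...) {
  cat(sprintf("rower chain config: N = %d, ring length = %g, mechanism = %s\n",
              x$spec$n_rowers, x$ring_length, x$spec$mechanism))
  invisible(x)
}
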