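#' Write a chain specification to a JSON config file
#'
#' Mechanism-specific keys are nested under \code{control}.  Lengths are in
#' bead radii, times in seconds, angles in radians.
#'
#' @param spec a [chain_spec()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_chain_spec <- function(spec, path) {
  stopifnot(inherits(spec, "chain_spec"))
  obj <- list(
    n_rowers = spec$n_rowers,
    bead_radius = spec$bead_radius,
    spacing = spec$spacing,
    height = spec$height,
    amplitude = spec$amplitude,
    tilt_angle = spec$tilt_angle,
    switch_offset = spec$switch_offset,
    force_exponent = spec$force_exponent,
    target_period_s = spec$target_period,
    noise_level = spec$noise_level,
    viscosity = spec$viscosity,
    control = list(mechanism = spec$mechanism,
                   group_size = spec$group_size,
                   d_X = spec$d_X, A_X = spec$A_X, f_X = spec$f_X)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a chain specification from a JSON config file
#'
#' @param path config file written by [write_chain_spec()] (missing keys fall
#'   back to the package defaults).
#' @return a [chain_spec()].
#' @export
read_chain_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctrl <- obj$control
  obj$control <- NULL
  if (!is.null(obj$target_period_s)) {
    obj$target_period <- obj$target_period_s
    obj$target_period_s <- NULL
  }
  args <- obj
  if (!is.null(ctrl)) {
    if (!is.null(ctrl$mechanism)) args$mechanism <- ctrl$mechanism
    for (key in c("group_size", "d_X", "A_X", "f_X"))
      if (!is.null(ctrl[[key]])) args[[key]] <- ctrl[[key]]
  }
  do.call(chain_spec, args)
}

#' Export a trajectory as a flat CSV
#'
#' One row per (sample, rower): \code{time_cycles}, \code{rower_index}
#' (1-based), \code{u_over_a}, \code{sigma}, \code{phase}.
#'
#' @param traj a \code{rower_trajectory}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
export_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "rower_trajectory"))
  n <- traj$config$spec$n_rowers
  ns <- length(traj$times)
  a <- traj$config$spec$bead_radius
  Ai <- rep(traj$config$amplitude_i, each = ns)
  df <- data.frame(
    time_cycles = rep(traj$times_cycles, times = n),
    rower_index = rep(seq_len(n), each = ns),
    u_over_a = as.vector(traj$u) / a,
    sigma = as.integer(as.vector(traj$sigma)),
    phase = geometric_phase(as.vector(traj$u), as.vector(traj$sigma), Ai)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-snapshot chevron analysis of a trajectory
#'
#' @param traj a \code{rower_trajectory}.
#' @param snap_times_cycles snapshot times (default: once per cycle over the
#'   final 5 percent of the run).
#' @param threshold detection threshold.
#' @return data.frame with time_cycles, chevron_count, dominant_mode,
#'   max_coefficient.
#' @export
analyze_trajectory <- function(traj, snap_times_cycles = NULL,
                               threshold = 0.15) {
  if (is.null(snap_times_cycles)) {
    t_end <- max(traj$times_cycles)
    snap_times_cycles <- seq(ceiling(0.95 * t_end), floor(t_end), by = 1)
  }
  rows <- lapply(snap_times_cycles, function(tt) {
    det <- detect_chevrons(fourier_coefficients(phase_profile(traj, tt)),
                           threshold = threshold)
    data.frame(time_cycles = tt, chevron_count = det$chevron_count,
               dominant_mode = det$dominant_mode,
               max_coefficient = det$max_coefficient)
  })
  do.call(rbind, rows)
}
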