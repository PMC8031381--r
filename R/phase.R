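#' Geometric phase of a rower
#'
#' Maps the (position, direction) pair of a rower onto a single cyclic
#' variable: the upstroke (sigma = +1) covers [0, pi) linearly in u and the
#' downstroke covers [pi, 2 pi), so the phase advances by 2 pi per beat and is
#' continuous at the switch points.  Positions that overshoot the switch point
#' (thermal noise fires the switch one step late) are clamped to the stroke
#' ends.
#'
#' @param u track coordinate (vectorised).
#' @param sigma trap orientation +1/-1 (vectorised).
#' @param amplitude beat amplitude A (vectorised; modified rowers use their
#'   own amplitude so the phase is per-rower normalised).
#' @return phase in [0, 2 pi).
#' @export
geometric_phase <- function(u, sigma, amplitude) {
  u <- pmin(pmax(u, -amplitude / 2), amplitude / 2)
  phi <- ifelse(sigma > 0,
                pi * (u + amplitude / 2) / amplitude,
                pi + pi * (amplitude / 2 - u) / amplitude)
  phi %% (2 * pi)
}

#' Wrap an angle into (-pi, pi]
#' @param x angle(s) in radians.
#' @return wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  out <- x - 2 * pi * round(x / (2 * pi))
  out[out <= -pi] <- out[out <= -pi] + 2 * pi
  out
}

#' Largest admissible spatial Fourier mode
#'
#' Modes smaller than three rowers in scale are discarded: the analysis keeps
#' k with N / (2k) > 3, i.e. k < N/6 (k < 10 for N = 60).
#'
#' @param n_rowers chain length N.
#' @return largest admissible mode number k_max.
#' @export
max_fourier_mode <- function(n_rowers) {
  stopifnot(n_rowers >= 7)
  as.integer(floor((n_rowers - 1) / 6))
}

#' Neighbour phase-difference profile at a snapshot
#'
#' For each ring edge i the wrapped difference
#' \eqn{\Delta\phi_i = \mathrm{wrap}(\phi_{i+1 \bmod N} - \phi_i)} in
#' (-pi, pi].  By construction the sum over the ring is 0 modulo 2 pi.
#'
#' @param traj a \code{rower_trajectory}.
#' @param t_cycles snapshot time in cycles (nearest stored sample is used).
#' @return object of class \code{phase_profile}: numeric vector of length N
#'   with attribute \code{snapshot_time} (cycles).
#' @export
phase_profile <- function(traj, t_cycles) {
  stopifnot(inherits(traj, "rower_trajectory"))
  tc <- traj$times_cycles
  if (t_cycles < min(tc) || t_cycles > max(tc))
    stop("snapshot time outside the trajectory")
  i <- which.min(abs(tc - t_cycles))
  phi <- geometric_phase(traj$u[i, ], traj$sigma[i, ],
                         traj$config$amplitude_i)
  new_phase_profile(wrap_angle(phi[c(2:length(phi), 1)] - phi),
                    snapshot_time = tc[i])
}

new_phase_profile <- function(values, snapshot_time = NA_real_) {
  structure(as.numeric(values), snapshot_time = snapshot_time,
            class = "phase_profile")
}

#' Spatial Fourier amplitudes of a phase profile
#'
#' Mode amplitudes \eqn{c_k = (2/N) |\sum_i \Delta\phi_i e^{-2\pi i k i /N}|}
#' for k = 1..k_max, normalised so a pure cosine of amplitude s gives
#' \eqn{c_k = s} (required for the detection threshold to read as a per-pair
#' phase difference).
#'
#' @param profile a \code{phase_profile} (or plain numeric vector).
#' @param k_max largest mode to report (default [max_fourier_mode()] of N).
#' @return named numeric vector c_1..c_{k_max}.
#' @export
fourier_coefficients <- function(profile, k_max = max_fourier_mode(length(profile))) {
  n <- length(profile)
  stopifnot(n >= 2 * k_max, k_max >= 1)
  X <- stats::fft(as.numeric(profile))
  ck <- 2 * Mod(X[seq_len(k_max) + 1]) / n
  names(ck) <- paste0("c", seq_len(k_max))
  ck
}

#' Detect chevrons in a phase profile's Fourier spectrum
#'
#' A chevron is a reversal of the sign of the neighbour phase difference (a
#' wedge in the phase profile); on a ring chevrons come in pairs, and a
#' profile holding k such pairs is a square wave in \eqn{\Delta\phi} whose
#' dominant spatial mode is k.  If every admissible coefficient is below the
#' threshold the structure is considered too small to indicate a chevron and
#' the count is zero; otherwise the count is the dominant mode number.  The
#' default threshold 0.15 corresponds to the per-pair phase difference
#' expected when every 40th rower is disrupted (2 pi / 40 ~ 0.157), structure
#' unlikely to arise spontaneously in a 60-rower chain.
#'
#' @param coeffs output of [fourier_coefficients()].
#' @param threshold detection threshold on the mode amplitude (default 0.15).
#' @return object of class \code{chevron_detection}: list with
#'   \code{coefficients}, \code{dominant_mode}, \code{max_coefficient},
#'   \code{above_threshold}, \code{chevron_count}.
#' @export
detect_chevrons <- function(coeffs, threshold = 0.15) {
  stopifnot(length(coeffs) >= 1, threshold > 0)
  kstar <- which.max(coeffs)
  cmax <- coeffs[[kstar]]
  above <- cmax >= threshold
  structure(list(coefficients = coeffs,
                 dominant_mode = as.integer(kstar),
                 max_coefficient = cmax,
                 above_threshold = above,
                 chevron_count = if (above) as.integer(kstar) else 0L),
            class = "chevron_detection")
}

#' Chevron count of one simulation run
#'
#' Applies the detector to snapshots taken once per cycle over the final
#' fraction of the run (steady-state window) and reports the modal count,
#' breaking frequency ties toward the count observed latest.
#'
#' @param traj a \code{rower_trajectory}.
#' @param window fraction of the run used as the steady-state window
#'   (default 0.05).
#' @param threshold detection threshold (default 0.15).
#' @return integer chevron count, with attributes \code{dominant_mode} and
#'   \code{max_coefficient} from the latest snapshot agreeing with the modal
#'   count.
#' @export
run_chevron_count <- function(traj, window = 0.05, threshold = 0.15) {
  stopifnot(inherits(traj, "rower_trajectory"), window > 0, window <= 1)
  t_end <- max(traj$times_cycles)
  t_start <- (1 - window) * t_end
  if (ceiling(t_start) > floor(t_end))
    stop("steady-state window shorter than one cycle: increase window or run length")
  snap_times <- seq(ceiling(t_start), floor(t_end), by = 1)
  dets <- lapply(snap_times, function(tt) {
    detect_chevrons(fourier_coefficients(phase_profile(traj, tt)),
                    threshold = threshold)
  })
  counts <- vapply(dets, `[[`, integer(1), "chevron_count")
  tab <- table(counts)
  modal <- as.integer(names(tab)[tab == max(tab)])
  # tie-break toward the latest snapshot showing one of the modal counts
  pick_i <- max(which(counts %in% modal))
  out <- counts[pick_i]
  attr(out, "dominant_mode") <- dets[[pick_i]]$dominant_mode
  attr(out, "max_coefficient") <- dets[[pick_i]]$max_coefficient
  out
}

#' @export
print.chevron_detection <- function(x, ...) {
  cat(sprintf("chevron detection: count = %d (dominant mode %d, c = %.3f, threshold %s)\n",
              x$chevron_count, x$dominant_mode, x$max_coefficient,
              if (x$above_threshold) "exceeded" else "not met"))
  invisible(x)
}
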