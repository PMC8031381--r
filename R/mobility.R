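#' Oseen tensor (bulk Stokeslet)
#'
#' Green's function of unbounded Stokes flow for a point force:
#' \eqn{G_{ij}(r) = (\delta_{ij} + \hat r_i \hat r_j) / (8 \pi \eta |r|)}.
#'
#' @param r_vec 3-vector separation (field minus source); must be non-zero.
#' @param viscosity dynamic viscosity eta.
#' @return 3 x 3 mobility tensor.
#' @export
oseen_block <- function(r_vec, viscosity = 1) {
  r <- sqrt(sum(r_vec^2))
  if (r == 0) stop("zero separation: the self term is handled separately")
  rhat <- r_vec / r
  (diag(3) + tcrossprod(rhat)) / (8 * pi * viscosity * r)
}

#' Blake tensor (Stokeslet near a plane no-slip wall)
#'
#' Green's function of Stokes flow bounded by a no-slip wall at z = 0, for a
#' unit point force at \code{source} evaluated at \code{field}.  Built from the
#' free-space Stokeslet plus Blake's image system at the mirror point: an
#' image Stokeslet, a Stokes doublet and a source doublet, whose strengths
#' depend on the source height.  The point-force (zero-radius) form is used;
#' finite-radius (Rotne-Prager / Faxen) corrections are omitted, consistent
#' with the far-field regime d/a = 7 the chain operates in.
#'
#' @param source 3-vector, strictly above the wall (z > 0).
#' @param field 3-vector, z >= 0, distinct from \code{source}.
#' @param viscosity dynamic viscosity eta.
#' @return 3 x 3 tensor G such that velocity = G \%*\% force.
#' @export
blake_block <- function(source, field, viscosity = 1) {
  if (source[3] <= 0) stop("source must lie strictly above the wall z = 0")
  if (field[3] < 0) stop("field point below the wall z = 0")
  r_vec <- field - source
  if (all(r_vec == 0)) stop("source and field points must be distinct")
  hs <- source[3]
  image <- c(source[1], source[2], -hs)
  R_vec <- field - image
  R <- sqrt(sum(R_vec^2))

  G <- oseen_block(r_vec, viscosity) - oseen_block(R_vec, viscosity)

  # 2 h M_k d/dR_k [ h R_i/R^3 - delta_i3/R - R_i R_3/R^3 ], M = (1, 1, -1)
  R3 <- R_vec[3]
  corr <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (k in 1:3) {
      dik <- as.numeric(i == k)
      di3 <- as.numeric(i == 3)
      d3k <- as.numeric(k == 3)
      bracket <- hs * (dik / R^3 - 3 * R_vec[i] * R_vec[k] / R^5) +
        di3 * R_vec[k] / R^3 -
        (dik * R3 + d3k * R_vec[i]) / R^3 +
        3 * R_vec[i] * R3 * R_vec[k] / R^5
      Mk <- if (k == 3) -1 else 1
      corr[i, k] <- 2 * hs * Mk * bracket
    }
  }
  G + corr / (8 * pi * viscosity)
}

#' Track-projected mobility matrix of a chain state
#'
#' Off-diagonal entry (i, j) is the track-tangential component of the Blake
#' coupling between beads j and i, \eqn{t^T G(p_j, p_i) t}, with the
#' x-separation wrapped by the minimum-image convention on the ring.  The
#' diagonal is the bulk self-mobility \eqn{1/(6\pi\eta a)} (no Faxen wall
#' correction; see package vignette).  The matrix is symmetrised and must be
#' positive definite for the Brownian noise factorisation.
#'
#' @param config a \code{chain_config}.
#' @param u numeric vector of track coordinates.
#' @param check_spd if TRUE (default), fail loudly when the symmetrised matrix
#'   is not positive definite rather than silently repairing it.
#' @return an N x N mobility matrix with attributes \code{viscosity} and
#'   \code{positions}.
#' @export
projected_mobility <- function(config, u, check_spd = TRUE) {
  spec <- config$spec
  n <- spec$n_rowers
  eta <- spec$viscosity
  pos <- bead_positions(config, u)
  t_hat <- config$track_direction
  M <- diag(n) / (6 * pi * eta * spec$bead_radius)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        dx <- minimum_image(pos[i, 1] - pos[j, 1], config$ring_length)
        fld <- c(pos[j, 1] + dx, pos[i, 2], pos[i, 3])
        G <- blake_block(pos[j, ], fld, eta)
        M[i, j] <- M[j, i] <- drop(t_hat %*% G %*% t_hat)
      }
    }
  }
  M <- (M + t(M)) / 2
  if (check_spd) {
    ok <- tryCatch({ chol(M); TRUE }, error = function(e) FALSE)
    if (!ok)
      stop("projected mobility matrix is not positive definite for this state")
  }
  structure(M, viscosity = eta, positions = pos)
}
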