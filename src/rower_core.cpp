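// Integrator core for the wall-bounded rower chain.
// Mobility = track-projected point-force Blake tensor, minimum image along x;
// noise via Cholesky of the mobility (Ermak-McCammon random step, no
// divergence drift: beads ride rigid 1-D tracks at fixed height).
// Drift uses a Heun (predictor-corrector) stage and the geometric switch is
// located within the step by linear interpolation: plain Euler with
// step-resolution switching biases the beat period by ~6 dt, well outside
// the calibration tolerance of one step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double min_image(double dx, double L) {
  double out = dx - L * std::nearbyint(dx / L);
  if (out <= -0.5 * L) out += L;
  return out;
}

// Tangential (t.G.t) Blake coupling between two beads at equal height h,
// track direction t = (c, s, 0).  dx, dy: field minus source, dz = 0.
static inline double blake_tangential(double dx, double dy, double h,
                                      double c, double s, double eta) {
  const double r2 = dx * dx + dy * dy;
  const double r = std::sqrt(r2);
  const double R2 = r2 + 4.0 * h * h;
  const double R = std::sqrt(R2);
  const double R3v = 2.0 * h;          // z-component of field - image
  const double tdotr = c * dx + s * dy;

  // Stokeslet(r) - Stokeslet(R), tangential projection
  double g = (1.0 / r + tdotr * tdotr / (r * r2)) -
             (1.0 / R + tdotr * tdotr / (R * R2));

  // image-system correction: i,k run over tangential components only
  // bracket_ik = h(d_ik/R^3 - 3 R_i R_k/R^5) - (d_ik R_3)/R^3 + 3 R_i R_3 R_k/R^5
  // (terms with d_i3 or d_3k vanish for tangential i,k), times 2h.
  const double R3i = 1.0 / (R * R2);
  const double R5i = R3i / R2;
  // t_i t_k d_ik = 1;  t_i t_k R_i R_k = tdotr^2
  double bracket = h * (R3i - 3.0 * tdotr * tdotr * R5i) -
                   R3v * R3i + 3.0 * tdotr * tdotr * R3v * R5i;
  g += 2.0 * h * bracket;

  return g / (8.0 * M_PI * eta);
}

static void fill_mobility(arma::mat &M, const arma::vec &x_center,
                          const arma::vec &u, double L, double h,
                          double c, double s, double a, double eta,
                          const arma::ivec &group, bool decouple) {
  const arma::uword n = M.n_rows;
  const double self = 1.0 / (6.0 * M_PI * eta * a);
  M.diag().fill(self);
  for (arma::uword i = 0; i + 1 < n; ++i) {
    for (arma::uword j = i + 1; j < n; ++j) {
      double val = 0.0;
      if (!decouple || group[i] == group[j]) {
        double dx = min_image((x_center[i] + u[i] * c) -
                              (x_center[j] + u[j] * c), L);
        double dy = (u[i] - u[j]) * s;
        val = blake_tangential(dx, dy, h, c, s, eta);
      }
      M(i, j) = val;
      M(j, i) = val;
    }
  }
}

// [[Rcpp::export]]
List rower_simulate_cpp(NumericVector track_x, double ring_length,
                        NumericVector amplitude, NumericVector trap_strength,
                        double switch_offset, double alpha,
                        double bead_radius, double height, double viscosity,
                        double tilt, double kBT, double dt,
                        int n_steps, int sample_every,
                        NumericVector u0, IntegerVector sigma0,
                        IntegerVector group_id, bool decouple_groups,
                        bool cache_mobility) {
  const int n = u0.size();
  const double c = std::cos(tilt), s = std::sin(tilt);

  arma::vec xc(track_x.begin(), n);
  arma::vec A(amplitude.begin(), n);
  arma::vec k(trap_strength.begin(), n);
  arma::ivec grp(n);
  for (int i = 0; i < n; ++i) grp[i] = group_id[i];

  arma::vec u(u0.begin(), n);
  arma::ivec sig(n);
  for (int i = 0; i < n; ++i) sig[i] = sigma0[i];

  const int n_samples = n_steps / sample_every + 1;
  arma::mat U(n_samples, n), S(n_samples, n);
  arma::vec times(n_samples);

  std::vector<double> sw_t;
  std::vector<int> sw_rower, sw_sign;

  arma::mat M(n, n), Lc(n, n);
  arma::vec Fv(n), F2(n), u_pred(n), u_old(n), z(n);
  const double self_mob = 1.0 / (6.0 * M_PI * viscosity * bead_radius);
  const double noise_pref = std::sqrt(2.0 * kBT * dt);
  const bool with_noise = kBT > 0.0;

  if (cache_mobility) {
    arma::vec u_zero(n, arma::fill::zeros);
    fill_mobility(M, xc, u_zero, ring_length, height, c, s,
                  bead_radius, viscosity, grp, decouple_groups);
    if (with_noise && !arma::chol(Lc, M, "lower"))
      stop("mobility matrix not positive definite at track centres");
  }

  int isample = 0;
  U.row(0) = u.t();
  for (int i = 0; i < n; ++i) S(0, i) = sig[i];
  times[0] = 0.0;
  isample = 1;

  RNGScope rngscope;  // draw thermal noise from R's RNG stream

  for (int step = 1; step <= n_steps; ++step) {
    if (!cache_mobility) {
      fill_mobility(M, xc, u, ring_length, height, c, s,
                    bead_radius, viscosity, grp, decouple_groups);
    }

    u_old = u;
    for (int i = 0; i < n; ++i) {
      double v = sig[i] * (0.5 * A[i] + switch_offset);
      double d = v - u[i];
      Fv[i] = alpha * k[i] * std::pow(std::fabs(d), alpha - 1.0) *
              (d > 0 ? 1.0 : -1.0);
    }
    // Heun corrector on the drift (mobility held at the start-of-step state:
    // its configuration dependence is a slow far-field correction)
    u_pred = u + (M * Fv) * dt;
    for (int i = 0; i < n; ++i) {
      double v = sig[i] * (0.5 * A[i] + switch_offset);
      double d = v - u_pred[i];
      if (d * sig[i] <= 0.0) { F2[i] = Fv[i]; continue; }  // predictor past vertex side
      F2[i] = alpha * k[i] * std::pow(std::fabs(d), alpha - 1.0) *
              (d > 0 ? 1.0 : -1.0);
    }
    u += (M * (0.5 * (Fv + F2))) * dt;

    if (with_noise) {
      if (!cache_mobility && !arma::chol(Lc, M, "lower"))
        stop("mobility matrix not positive definite at step %d", step);
      for (int i = 0; i < n; ++i) z[i] = R::norm_rand();
      u += noise_pref * (Lc * z);
    }

    double t_now = step * dt;
    for (int i = 0; i < n; ++i) {
      if (std::fabs(u[i]) > 0.5 * A[i] + switch_offset)
        stop("bead %d stepped past the trap vertex at t = %g: reduce dt",
             i + 1, t_now);
      if (sig[i] * u[i] >= 0.5 * A[i]) {
        // locate the crossing within the step and restart the reversed
        // stroke from the switch point for the remaining fraction
        double u_sw = sig[i] * 0.5 * A[i];
        double du = u[i] - u_old[i];
        double theta = 1.0;
        if (std::fabs(du) > 0.0) theta = (u_sw - u_old[i]) / du;
        if (theta < 0.0) theta = 0.0;
        if (theta > 1.0) theta = 1.0;
        sig[i] = -sig[i];
        double v = sig[i] * (0.5 * A[i] + switch_offset);
        double d = v - u_sw;
        double f_new = alpha * k[i] * std::pow(std::fabs(d), alpha - 1.0) *
                       (d > 0 ? 1.0 : -1.0);
        u[i] = u_sw + self_mob * f_new * (1.0 - theta) * dt;
        sw_t.push_back((step - 1 + theta) * dt);
        sw_rower.push_back(i + 1);
        sw_sign.push_back(sig[i]);
      }
    }

    if (step % sample_every == 0) {
      U.row(isample) = u.t();
      for (int i = 0; i < n; ++i) S(isample, i) = sig[i];
      times[isample] = t_now;
      ++isample;
    }
  }

  return List::create(
    _["times"] = NumericVector(times.begin(), times.begin() + isample),
    _["u"] = wrap(U.rows(0, isample - 1)),
    _["sigma"] = wrap(S.rows(0, isample - 1)),
    _["switch_times"] = wrap(sw_t),
    _["switch_rower"] = wrap(sw_rower),
    _["switch_sign"] = wrap(sw_sign));
}

// Exposed for cross-checking the pure-R mobility construction.
// [[Rcpp::export]]
arma::mat rower_mobility_cpp(NumericVector track_x, double ring_length,
                             NumericVector u, double bead_radius,
                             double height, double viscosity, double tilt,
                             IntegerVector group_id, bool decouple_groups) {
  const int n = u.size();
  arma::vec xc(track_x.begin(), n), uu(u.begin(), n);
  arma::ivec grp(n);
  for (int i = 0; i < n; ++i) grp[i] = group_id[i];
  arma::mat M(n, n);
  fill_mobility(M, xc, uu, ring_length, height,
                std::cos(tilt), std::sin(tilt),
                bead_radius, viscosity, grp, decouple_groups);
  return M;
}
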