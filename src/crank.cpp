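#include <Rcpp.h>
using namespace Rcpp;

// closed window, wrapping through 0/360 when start > end
static inline bool in_win(double th, double s, double e) {
  return (s <= e) ? (th >= s && th <= e) : (th >= s || th <= e);
}

// wrap an angle into [0, 360)
static inline double wrap360(double x) {
  x -= 360.0 * std::floor(x / 360.0);
  return (x >= 360.0 || x < 0.0) ? 0.0 : x;
}

// signed angular distance in (-180, 180]
static inline double ang_dist(double a, double b) {
  return wrap360(a - b + 180.0) - 180.0;
}

// Advance the crank + per-channel fatigue dynamics over nsub substeps of
// dt/nsub while the stimulation commands (charge rates) are held constant.
// Semi-implicit Euler on the damped crank; cadence floored at zero.
// [[Rcpp::export]]
List crank_advance_cpp(double theta, double theta_total, double cadence_rpm,
                       NumericVector fitness, NumericVector charge,
                       NumericVector win_start, NumericVector win_end,
                       NumericVector center, NumericVector half_width,
                       NumericVector peak, LogicalVector flat,
                       double q0, double qsat, double J, double b,
                       double tau_load, double lambda, double rho,
                       double phi_min, double torque_gain,
                       double dt, int nsub) {
  const int nc = fitness.size();
  if (nsub < 1) nsub = 1;
  NumericVector phi = clone(fitness);
  double omega = cadence_rpm * M_PI / 30.0;  // rad/s
  const double h = dt / nsub;
  double power_acc = 0.0;

  for (int k = 0; k < nsub; ++k) {
    double tau_m = 0.0;
    for (int c = 0; c < nc; ++c) {
      double act = 0.0;
      if (charge[c] > 0.0 && in_win(theta, win_start[c], win_end[c])) {
        double rec = (charge[c] - q0) / (qsat - q0);
        if (rec < 0.0) rec = 0.0;
        if (rec > 1.0) rec = 1.0;
        act = rec * phi[c];
        double d = ang_dist(theta, center[c]);
        if (std::fabs(d) <= half_width[c]) {
          double g = flat[c] ? peak[c]
                             : peak[c] * 0.5 * (1.0 + std::cos(M_PI * d / half_width[c]));
          tau_m += act * g;
        }
      }
      phi[c] += h * (-lambda * act * (phi[c] - phi_min)
                     + rho * (1.0 - phi[c]) * (1.0 - act));
      if (phi[c] < phi_min) phi[c] = phi_min;
      if (phi[c] > 1.0) phi[c] = 1.0;
    }
    tau_m *= torque_gain;
    omega = (omega + h * (tau_m - tau_load) / J) / (1.0 + h * b / J);
    if (omega < 0.0) omega = 0.0;
    double dtheta = omega * h * 180.0 / M_PI;
    theta = wrap360(theta + dtheta);
    theta_total += dtheta;
    power_acc += tau_m * omega;
  }

  if (!std::isfinite(theta) || !std::isfinite(omega))
    stop("crank dynamics diverged (non-finite state)");

  return List::create(_["theta"] = theta,
                      _["theta_total"] = theta_total,
                      _["cadence_rpm"] = omega * 30.0 / M_PI,
                      _["fitness"] = phi,
                      _["power_w"] = power_acc / nsub);
}
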