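#include <Rcpp.h>
using namespace Rcpp;

// Sigmoidal self-replacement f(Y) = (Y/h)^p / ((Y/h)^p + 1), with the p = 0
// case fixed at 1/2 (continuity in Y > 0). Computed on the (Y/h)^p ratio
// scale so that large p does not overflow.
static inline double self_rep(double y, double p, double h) {
  if (p == 0.0) return 0.5;
  if (y <= 0.0) return 0.0;
  double z = std::pow(y / h, p);
  if (!R_finite(z)) return 1.0;  // (Y/h)^p overflowed: f has saturated
  return z / (z + 1.0);
}

static inline double drift_c(double y, double a, double b, double r, double p,
                             double h) {
  return a - b * y + r * self_rep(y, p, h);
}

// Triangular driver: piecewise linear between the ramp extremes, reaching the
// far extreme at t = total_steps / 2 and returning at t = total_steps.
static inline double driver_c(double t, double a_low, double a_high,
                              double total_steps, bool up_first) {
  double frac = t / total_steps;
  double tri = 1.0 - std::fabs(1.0 - 2.0 * frac);
  if (tri < 0.0) tri = 0.0;
  if (tri > 1.0) tri = 1.0;
  return up_first ? a_low + (a_high - a_low) * tri
                  : a_high - (a_high - a_low) * tri;
}

// Classical fixed-step RK4 for dY/dt = a(t) - b Y + r f(Y) under the
// triangular ramp. Returns Y at the unit timesteps t = 0, 1, ..., total_steps.
// [[Rcpp::export]]
NumericVector rk4_ramp(double y0, double b, double r, double h, double p,
                       double a_low, double a_high, int total_steps,
                       int substeps, bool up_first) {
  NumericVector out(total_steps + 1);
  out[0] = y0;
  double y = y0;
  double dt = 1.0 / substeps;
  double T = static_cast<double>(total_steps);
  for (int step = 0; step < total_steps; ++step) {
    for (int s = 0; s < substeps; ++s) {
      double t0 = step + s * dt;
      double a1 = driver_c(t0, a_low, a_high, T, up_first);
      double a2 = driver_c(t0 + 0.5 * dt, a_low, a_high, T, up_first);
      double a4 = driver_c(t0 + dt, a_low, a_high, T, up_first);
      double k1 = drift_c(y, a1, b, r, p, h);
      double k2 = drift_c(y + 0.5 * dt * k1, a2, b, r, p, h);
      double k3 = drift_c(y + 0.5 * dt * k2, a2, b, r, p, h);
      double k4 = drift_c(y + dt * k3, a4, b, r, p, h);
      y += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      if (y < 0.0) y = 0.0;  // state is a nonnegative ecosystem property
      if (!R_finite(y)) stop("integration diverged at t = %f", t0);
    }
    out[step + 1] = y;
  }
  return out;
}

// Constant-driver companion used for equilibration checks.
// [[Rcpp::export]]
NumericVector rk4_constant(double y0, double b, double r, double h, double p,
                           double a, int total_steps, int substeps) {
  NumericVector out(total_steps + 1);
  out[0] = y0;
  double y = y0;
  double dt = 1.0 / substeps;
  for (int step = 0; step < total_steps; ++step) {
    for (int s = 0; s < substeps; ++s) {
      double k1 = drift_c(y, a, b, r, p, h);
      double k2 = drift_c(y + 0.5 * dt * k1, a, b, r, p, h);
      double k3 = drift_c(y + 0.5 * dt * k2, a, b, r, p, h);
      double k4 = drift_c(y + dt * k3, a, b, r, p, h);
      y += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      if (y < 0.0) y = 0.0;
      if (!R_finite(y)) stop("integration diverged");
    }
    out[step + 1] = y;
  }
  return out;
}
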