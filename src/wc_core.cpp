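// Core numerics: Wilson-Cowan vector field, deterministic integrators
// (fixed-step Euler, adaptive Dormand-Prince RK45), Euler-Maruyama SDE
// engine with in-loop stimulation controllers, isostable amplitude
// evaluation, and the discretized response-field algorithms.
//
// All stochastic code draws from R's RNG (norm_rand) so that set.seed()
// on the R side gives bit-reproducible trajectories.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// model
// ---------------------------------------------------------------------------

struct WCParams {
  double nu, beta, eta_E, eta_I, w_EE, w_IE, w_EI, zeta;
};

static WCParams unpack(const NumericVector& pv) {
  WCParams p;
  p.nu = pv[0]; p.beta = pv[1]; p.eta_E = pv[2]; p.eta_I = pv[3];
  p.w_EE = pv[4]; p.w_IE = pv[5]; p.w_EI = pv[6]; p.zeta = pv[7];
  return p;
}

static inline double sigf(double x, double beta) {
  // logistic with inflection at x = 1; saturates without overflow
  return 1.0 / (1.0 + std::exp(-beta * (x - 1.0)));
}

static inline void wc_drift(const WCParams& p, double E, double I,
                            double& dE, double& dI) {
  dE = (-E + sigf(p.eta_E + p.w_EE * E - p.w_IE * I, p.beta)) / p.nu;
  dI = (-I + sigf(p.eta_I + p.w_EI * E, p.beta)) / p.nu;
}

// [[Rcpp::export]]
NumericVector cpp_sigmoid(NumericVector x, double beta) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = sigf(x[i], beta);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_drift(NumericVector state, NumericVector pv) {
  WCParams p = unpack(pv);
  double dE, dI;
  wc_drift(p, state[0], state[1], dE, dI);
  return NumericVector::create(dE, dI);
}

// [[Rcpp::export]]
NumericMatrix cpp_jacobian(NumericVector state, NumericVector pv) {
  WCParams p = unpack(pv);
  double uE = p.eta_E + p.w_EE * state[0] - p.w_IE * state[1];
  double uI = p.eta_I + p.w_EI * state[0];
  double fE = sigf(uE, p.beta), fI = sigf(uI, p.beta);
  double dfE = p.beta * fE * (1.0 - fE);
  double dfI = p.beta * fI * (1.0 - fI);
  NumericMatrix J(2, 2);
  J(0, 0) = (-1.0 + dfE * p.w_EE) / p.nu;
  J(0, 1) = -dfE * p.w_IE / p.nu;
  J(1, 0) = dfI * p.w_EI / p.nu;
  J(1, 1) = -1.0 / p.nu;
  return J;
}

// ---------------------------------------------------------------------------
// deterministic integration
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_integrate_euler(NumericVector x0, NumericVector pv,
                                  int n_steps, double dt) {
  WCParams p = unpack(pv);
  NumericMatrix out(n_steps + 1, 2);
  double E = x0[0], I = x0[1], dE, dI;
  out(0, 0) = E; out(0, 1) = I;
  for (int i = 0; i < n_steps; ++i) {
    wc_drift(p, E, I, dE, dI);
    E += dE * dt;
    I += dI * dt;
    if (!std::isfinite(E) || !std::isfinite(I))
      stop("non-finite state at step %d", i + 1);
    out(i + 1, 0) = E; out(i + 1, 1) = I;
  }
  return out;
}

// Dormand-Prince 5(4) pair with FSAL
struct DP45 {
  const WCParams p;
  double rtol, atol, hmax;
  explicit DP45(const WCParams& p_, double rtol_, double atol_, double hmax_)
    : p(p_), rtol(rtol_), atol(atol_), hmax(hmax_) {}

  // advance (y, t) by one accepted step; k1 holds f(t, y) on entry and
  // f(t+h, y) on exit (FSAL). h_did/h_next report step sizes.
  void step(double y[2], double& t, double& h, double k1[2],
            double& h_did) {
    static const double a21 = 1.0 / 5.0;
    static const double a31 = 3.0 / 40.0, a32 = 9.0 / 40.0;
    static const double a41 = 44.0 / 45.0, a42 = -56.0 / 15.0, a43 = 32.0 / 9.0;
    static const double a51 = 19372.0 / 6561.0, a52 = -25360.0 / 2187.0,
      a53 = 64448.0 / 6561.0, a54 = -212.0 / 729.0;
    static const double a61 = 9017.0 / 3168.0, a62 = -355.0 / 33.0,
      a63 = 46732.0 / 5247.0, a64 = 49.0 / 176.0, a65 = -5103.0 / 18656.0;
    static const double b1 = 35.0 / 384.0, b3 = 500.0 / 1113.0,
      b4 = 125.0 / 192.0, b5 = -2187.0 / 6784.0, b6 = 11.0 / 84.0;
    static const double e1 = b1 - 5179.0 / 57600.0, e3 = b3 - 7571.0 / 16695.0,
      e4 = b4 - 393.0 / 640.0, e5 = b5 + 92097.0 / 339200.0,
      e6 = b6 - 187.0 / 2100.0, e7 = -1.0 / 40.0;

    double k2[2], k3[2], k4[2], k5[2], k6[2], k7[2], yt[2], ynew[2];
    for (int it = 0; it < 200; ++it) {
      if (h > hmax) h = hmax;
      for (int d = 0; d < 2; ++d) yt[d] = y[d] + h * a21 * k1[d];
      wc_drift(p, yt[0], yt[1], k2[0], k2[1]);
      for (int d = 0; d < 2; ++d) yt[d] = y[d] + h * (a31 * k1[d] + a32 * k2[d]);
      wc_drift(p, yt[0], yt[1], k3[0], k3[1]);
      for (int d = 0; d < 2; ++d)
        yt[d] = y[d] + h * (a41 * k1[d] + a42 * k2[d] + a43 * k3[d]);
      wc_drift(p, yt[0], yt[1], k4[0], k4[1]);
      for (int d = 0; d < 2; ++d)
        yt[d] = y[d] + h * (a51 * k1[d] + a52 * k2[d] + a53 * k3[d] + a54 * k4[d]);
      wc_drift(p, yt[0], yt[1], k5[0], k5[1]);
      for (int d = 0; d < 2; ++d)
        yt[d] = y[d] + h * (a61 * k1[d] + a62 * k2[d] + a63 * k3[d] +
                            a64 * k4[d] + a65 * k5[d]);
      wc_drift(p, yt[0], yt[1], k6[0], k6[1]);
      for (int d = 0; d < 2; ++d)
        ynew[d] = y[d] + h * (b1 * k1[d] + b3 * k3[d] + b4 * k4[d] +
                              b5 * k5[d] + b6 * k6[d]);
      wc_drift(p, ynew[0], ynew[1], k7[0], k7[1]);

      double errnorm = 0.0;
      for (int d = 0; d < 2; ++d) {
        double err = h * (e1 * k1[d] + e3 * k3[d] + e4 * k4[d] +
                          e5 * k5[d] + e6 * k6[d] + e7 * k7[d]);
        double sc = atol + rtol * std::max(std::fabs(y[d]), std::fabs(ynew[d]));
        double r = err / sc;
        errnorm += r * r;
      }
      errnorm = std::sqrt(errnorm / 2.0);
      if (!std::isfinite(errnorm)) { h *= 0.5; continue; }
      if (errnorm <= 1.0) {
        h_did = h;
        t += h;
        for (int d = 0; d < 2; ++d) { y[d] = ynew[d]; k1[d] = k7[d]; }
        double fac = (errnorm == 0.0) ? 5.0
          : std::min(5.0, std::max(0.2, 0.9 * std::pow(errnorm, -0.2)));
        h *= fac;
        return;
      }
      h *= std::max(0.2, 0.9 * std::pow(errnorm, -0.2));
    }
    stop("RK45 step-size control failed to converge");
  }
};

// cubic Hermite interpolation between accepted steps (dense output)
static inline void hermite(const double y0[2], const double f0[2],
                           const double y1[2], const double f1[2],
                           double h, double theta, double out[2]) {
  double t2 = theta * theta, t3 = t2 * theta;
  double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + theta;
  double h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
  for (int d = 0; d < 2; ++d)
    out[d] = h00 * y0[d] + h * h10 * f0[d] + h01 * y1[d] + h * h11 * f1[d];
}

// [[Rcpp::export]]
NumericMatrix cpp_integrate_rk45(NumericVector x0, NumericVector pv,
                                 int n_steps, double dt_out,
                                 double rtol, double atol) {
  WCParams p = unpack(pv);
  DP45 solver(p, rtol, atol, std::max(dt_out, (n_steps * dt_out) / 10.0));
  NumericMatrix out(n_steps + 1, 2);
  double y[2] = { x0[0], x0[1] }, f[2];
  wc_drift(p, y[0], y[1], f[0], f[1]);
  out(0, 0) = y[0]; out(0, 1) = y[1];
  double t = 0.0, h = dt_out;
  int next = 1;
  double yprev[2], fprev[2], tprev;
  while (next <= n_steps) {
    tprev = t;
    yprev[0] = y[0]; yprev[1] = y[1];
    fprev[0] = f[0]; fprev[1] = f[1];
    double h_did;
    solver.step(y, t, h, f, h_did);
    if (!std::isfinite(y[0]) || !std::isfinite(y[1]))
      stop("non-finite state at t=%g", t);
    while (next <= n_steps && next * dt_out <= t + 1e-12 * dt_out) {
      double theta = (next * dt_out - tprev) / h_did;
      if (theta > 1.0) theta = 1.0;
      double yi[2];
      hermite(yprev, fprev, y, f, h_did, theta, yi);
      out(next, 0) = yi[0]; out(next, 1) = yi[1];
      ++next;
    }
    if ((next % 4096) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Deviation-coordinate integration for the amplitude map: the state is
// y = X - X*, with the floating-point drift residual at X* subtracted so
// y = 0 is an exact equilibrium.  Controlling the RK45 error relative to
// |y| keeps the *relative* accuracy of the exponentially decaying
// observables, which an absolute-coordinate integration cannot do.
struct DevField {
  WCParams p;
  double xs[2]; // fixed point
  double F0[2]; // drift residual at the fixed point (roundoff-level)
  void drift(double yE, double yI, double& dE, double& dI) const {
    wc_drift(p, xs[0] + yE, xs[1] + yI, dE, dI);
    dE -= F0[0];
    dI -= F0[1];
  }
};

// Dormand-Prince 5(4) on the deviation equation, endpoint only; returns
// false if the trajectory leaves `box` (divergence / outside basin)
static bool rk45_endpoint_dev(const DevField& fld, double y[2], double t_end,
                              double rtol, double atol, const double box[4]) {
  static const double a21 = 1.0 / 5.0;
  static const double a31 = 3.0 / 40.0, a32 = 9.0 / 40.0;
  static const double a41 = 44.0 / 45.0, a42 = -56.0 / 15.0, a43 = 32.0 / 9.0;
  static const double a51 = 19372.0 / 6561.0, a52 = -25360.0 / 2187.0,
    a53 = 64448.0 / 6561.0, a54 = -212.0 / 729.0;
  static const double a61 = 9017.0 / 3168.0, a62 = -355.0 / 33.0,
    a63 = 46732.0 / 5247.0, a64 = 49.0 / 176.0, a65 = -5103.0 / 18656.0;
  static const double b1 = 35.0 / 384.0, b3 = 500.0 / 1113.0,
    b4 = 125.0 / 192.0, b5 = -2187.0 / 6784.0, b6 = 11.0 / 84.0;
  static const double e1 = b1 - 5179.0 / 57600.0, e3 = b3 - 7571.0 / 16695.0,
    e4 = b4 - 393.0 / 640.0, e5 = b5 + 92097.0 / 339200.0,
    e6 = b6 - 187.0 / 2100.0, e7 = -1.0 / 40.0;
  double hmax = t_end / 4.0;
  double k1[2], k2[2], k3[2], k4[2], k5[2], k6[2], k7[2], yt[2], ynew[2];
  fld.drift(y[0], y[1], k1[0], k1[1]);
  double t = 0.0, h = std::min(1e-3, t_end);
  int guard = 0;
  while (t < t_end) {
    if (++guard > 100000000) stop("RK45 failed to reach the end time");
    if (h > hmax) h = hmax;
    if (t + h > t_end) h = t_end - t;
    for (int d = 0; d < 2; ++d) yt[d] = y[d] + h * a21 * k1[d];
    fld.drift(yt[0], yt[1], k2[0], k2[1]);
    for (int d = 0; d < 2; ++d) yt[d] = y[d] + h * (a31 * k1[d] + a32 * k2[d]);
    fld.drift(yt[0], yt[1], k3[0], k3[1]);
    for (int d = 0; d < 2; ++d)
      yt[d] = y[d] + h * (a41 * k1[d] + a42 * k2[d] + a43 * k3[d]);
    fld.drift(yt[0], yt[1], k4[0], k4[1]);
    for (int d = 0; d < 2; ++d)
      yt[d] = y[d] + h * (a51 * k1[d] + a52 * k2[d] + a53 * k3[d] + a54 * k4[d]);
    fld.drift(yt[0], yt[1], k5[0], k5[1]);
    for (int d = 0; d < 2; ++d)
      yt[d] = y[d] + h * (a61 * k1[d] + a62 * k2[d] + a63 * k3[d] +
                          a64 * k4[d] + a65 * k5[d]);
    fld.drift(yt[0], yt[1], k6[0], k6[1]);
    for (int d = 0; d < 2; ++d)
      ynew[d] = y[d] + h * (b1 * k1[d] + b3 * k3[d] + b4 * k4[d] +
                            b5 * k5[d] + b6 * k6[d]);
    fld.drift(ynew[0], ynew[1], k7[0], k7[1]);
    double ymag = std::max(std::max(std::fabs(y[0]), std::fabs(y[1])),
                           std::max(std::fabs(ynew[0]), std::fabs(ynew[1])));
    double errnorm = 0.0;
    for (int d = 0; d < 2; ++d) {
      double err = h * (e1 * k1[d] + e3 * k3[d] + e4 * k4[d] +
                        e5 * k5[d] + e6 * k6[d] + e7 * k7[d]);
      double sc = atol + rtol * ymag; // scale on the deviation magnitude
      double r = err / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / 2.0);
    if (!std::isfinite(errnorm)) { h *= 0.5; continue; }
    if (errnorm <= 1.0) {
      t += h;
      for (int d = 0; d < 2; ++d) { y[d] = ynew[d]; k1[d] = k7[d]; }
      double fac = (errnorm == 0.0) ? 5.0
        : std::min(5.0, std::max(0.2, 0.9 * std::pow(errnorm, -0.2)));
      h *= fac;
      double E = fld.xs[0] + y[0], I = fld.xs[1] + y[1];
      if (!std::isfinite(E) || !std::isfinite(I) ||
          E < box[0] || E > box[1] || I < box[2] || I > box[3])
        return false;
    } else {
      h *= std::max(0.2, 0.9 * std::pow(errnorm, -0.2));
    }
  }
  return true;
}

static bool euler_endpoint_dev(const DevField& fld, double y[2], double t_end,
                               double dt, const double box[4]) {
  long n = std::lround(t_end / dt);
  double dE, dI;
  for (long i = 0; i < n; ++i) {
    fld.drift(y[0], y[1], dE, dI);
    y[0] += dE * dt;
    y[1] += dI * dt;
    double E = fld.xs[0] + y[0], I = fld.xs[1] + y[1];
    if (!std::isfinite(E) || !std::isfinite(I) ||
        E < box[0] || E > box[1] || I < box[2] || I > box[3])
      return false;
  }
  return true;
}

// ---------------------------------------------------------------------------
// isostable amplitude (map-based estimate at t = n T)
// ---------------------------------------------------------------------------

// r(X) ~ e^{-sigma n T} sqrt(g1^2 + g2^2) / |b2 a1 - b1 a2|
// with g1, g2 the linear observables evaluated at the flow endpoint.
// [[Rcpp::export]]
NumericVector cpp_iso_amp(NumericMatrix X, NumericVector pv,
                          NumericVector xstar, double sigma,
                          NumericVector a, NumericVector b,
                          double total_time, bool use_euler,
                          double euler_dt, double rtol, double atol,
                          NumericVector box) {
  DevField fld;
  fld.p = unpack(pv);
  fld.xs[0] = xstar[0]; fld.xs[1] = xstar[1];
  wc_drift(fld.p, fld.xs[0], fld.xs[1], fld.F0[0], fld.F0[1]);
  double denom = std::fabs(b[1] * a[0] - b[0] * a[1]);
  double bx[4] = { box[0], box[1], box[2], box[3] };
  double pref = std::exp(-sigma * total_time);
  R_xlen_t m = X.nrow();
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    double y[2] = { X(i, 0) - xstar[0], X(i, 1) - xstar[1] };
    if (y[0] == 0.0 && y[1] == 0.0) { out[i] = 0.0; continue; }
    bool ok = use_euler
      ? euler_endpoint_dev(fld, y, total_time, euler_dt, bx)
      : rk45_endpoint_dev(fld, y, total_time, rtol, atol, bx);
    if (!ok) {
      out[i] = NA_REAL;
    } else {
      double g1 = y[0] * b[1] - y[1] * b[0];
      double g2 = y[0] * a[1] - y[1] * a[0];
      out[i] = pref * std::sqrt(g1 * g1 + g2 * g2) / denom;
    }
    if ((i % 256) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// phase tracking (zero-crossing phase, shared by controller and baseline)
// ---------------------------------------------------------------------------

struct PhaseTracker {
  long n0;              // step of current period start (last + crossing)
  long period_steps;    // previous period duration in steps
  long n1;              // predicted period end step
  int ncross;
  double phase;
  double prev_ec;
  bool stim_this_period;

  explicit PhaseTracker(long bootstrap_steps)
    : n0(0), period_steps(bootstrap_steps), n1(bootstrap_steps), ncross(0),
      phase(0.0), prev_ec(NA_REAL), stim_this_period(false) {}

  // returns true on a positive zero-crossing at step i
  bool update(double ec, long i) {
    bool cross = (i > 0 && prev_ec < 0.0 && ec >= 0.0);
    if (cross) {
      // bootstrap: until the second crossing the previous period is unknown
      if (ncross >= 1) period_steps = i - n0;
      n0 = i;
      n1 = n0 + period_steps;
      phase = 0.0;
      ++ncross;
    } else if (i > 0) {
      phase += 2.0 * M_PI / (double)period_steps;
      // wrap into [0, 2*pi) (avoiding fmod keeps the binary portable
      // across glibc versions)
      phase -= 2.0 * M_PI * std::floor(phase / (2.0 * M_PI));
    }
    prev_ec = ec;
    return cross;
  }
};

// [[Rcpp::export]]
List cpp_track_phase(NumericVector ec, double dt, int bootstrap_steps) {
  R_xlen_t n = ec.size();
  PhaseTracker tr(bootstrap_steps);
  NumericVector phase(n);
  IntegerVector n0v(n), n1v(n);
  std::vector<int> crossings;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (tr.update(ec[i], i)) crossings.push_back((int)i + 1); // 1-based
    phase[i] = tr.phase;
    n0v[i] = (int)tr.n0 + 1;
    n1v[i] = (int)tr.n1 + 1;
  }
  return List::create(_["phase"] = phase, _["n0"] = n0v, _["n1"] = n1v,
                      _["crossings"] = wrap(crossings));
}

// ---------------------------------------------------------------------------
// Eq-5 temporal discount factor
// ---------------------------------------------------------------------------

// alpha for lookahead k (k >= 1) at step i, period window [n0, n1], with
// t measured in steps * dt.  alpha = 1 at k = 1 and 0 at i + k - 1 = n1.
static double discount_core(long i, long k, long n0, long n1,
                            double b, double dt) {
  if (n1 == n0) stop("degenerate period window (n1 == n0)");
  if (k == 1) return 1.0;
  double xi = (double)(i - n0) * dt;          // t_i - t_n0
  double xk = (double)(i + k - 1 - n0) * dt;  // t_{i+k-1} - t_n0
  double xn = (double)(n1 - n0) * dt;         // t_n1 - t_n0
  if (std::fabs(b) < 1e-12) {
    // b -> 0 limit of Eq 5 (log form)
    if (xi <= 0.0) return 0.0;
    return std::log(xn / xk) / std::log(xn / xi);
  }
  if (xi <= 0.0) {
    // t_i = t_n0: for b > 0 the present value diverges -> full discount;
    // for b < 0 take the finite limit 1 - (xk/xn)^{-b}
    if (b > 0.0) return 0.0;
    return 1.0 - std::pow(xk / xn, -b);
  }
  double num = std::pow(xk, -b) - std::pow(xn, -b);
  double den = std::pow(xi, -b) - std::pow(xn, -b);
  if (den == 0.0) return 0.0;
  double alpha = num / den;
  if (alpha < 0.0) alpha = 0.0;
  if (alpha > 1.0) alpha = 1.0;
  return alpha;
}

// [[Rcpp::export]]
double cpp_discount(double i, double k, double n0, double n1,
                    double b, double dt) {
  return discount_core((long)i, (long)k, (long)n0, (long)n1, b, dt);
}

// ---------------------------------------------------------------------------
// Algorithm 2 decision core (single bin column of Gamma)
// ---------------------------------------------------------------------------

// g: pointer to Gamma(p, q, .) values, stride between lookahead slices,
// depth u.  Assumes eligibility (rate cap, once-per-period) already checked.
static bool algo2_core(const double* g, R_xlen_t stride, int u,
                       long i, long n0, long n1, double b, double dt) {
  double g1 = g[0];
  if (!(g1 < 0.0)) return false;
  if (i >= n1) return true;          // predicted period end already reached
  long kmax = std::min((long)u, n1 - i + 1);
  double m = R_PosInf;
  for (long k = 2; k <= kmax; ++k) {
    double alpha = discount_core(i, k, n0, n1, b, dt);
    double v = alpha * g[(k - 1) * stride];
    if (v < m) m = v;
  }
  if (kmax < 2) return true;         // no future to wait for
  return g1 < m;
}

// [[Rcpp::export]]
bool cpp_decide_core(NumericVector g, double i, double n0, double n1,
                     double b, double dt) {
  return algo2_core(REAL(g), 1, (int)g.size(), (long)i, (long)n0, (long)n1,
                    b, dt);
}

// ---------------------------------------------------------------------------
// SDE engine with in-loop stimulation
// ---------------------------------------------------------------------------

struct GridSpec {
  double e0, de, i0, di;
  int nE, nI;
};

static inline int bin_index_1d(double x, double lo, double w, int n) {
  double u = (x - lo) / w;
  if (u < 0.0 || u >= (double)n) return -1;
  int k = (int)std::floor(u);
  // exact boundary is equidistant between neighbouring centers: lower wins
  if ((double)k == u && k > 0) --k;
  if (k >= n) k = n - 1;
  return k;
}

// mode: 0 none, 1 open-loop HF, 2 phase-locked, 3 phase-space (Algorithm 2)
// [[Rcpp::export]]
List cpp_sde_run(NumericVector x0, NumericVector pv, double n_steps_d,
                 double dt, double zeta_scale, bool noise_inside_nu,
                 int mode, List ctrl, bool store_I) {
  WCParams p = unpack(pv);
  long n_steps = (long)n_steps_d;
  double sig = p.zeta * zeta_scale * std::sqrt(dt);
  if (noise_inside_nu) sig /= p.nu;

  // controller setup -------------------------------------------------------
  double dE_pulse = 0.0;
  long hf_interval = 0;
  double target_phase = 0.0;
  long Nlim = 0, bootstrap_steps = 0;
  double b_disc = 0.0, estar = 0.0;
  long cwin = 0;
  GridSpec gs = {0, 1, 0, 1, 0, 0};
  double* gamma = nullptr;
  int u_depth = 0;
  if (mode != 0) {
    dE_pulse = as<double>(ctrl["dE"]);
  }
  if (mode == 1) {
    hf_interval = (long)as<double>(ctrl["interval_steps"]);
  }
  if (mode == 2 || mode == 3) {
    bootstrap_steps = (long)as<double>(ctrl["bootstrap_steps"]);
    estar = as<double>(ctrl["e_star"]);
    cwin = (long)as<double>(ctrl["centering_window_steps"]);
  }
  if (mode == 2) target_phase = as<double>(ctrl["target_phase"]);
  NumericVector gamma_keepalive;
  if (mode == 3) {
    Nlim = (long)as<double>(ctrl["n_lim"]);
    b_disc = as<double>(ctrl["b"]);
    gamma_keepalive = as<NumericVector>(ctrl["gamma"]);
    gamma = REAL(gamma_keepalive);
    IntegerVector dims = gamma_keepalive.attr("dim");
    gs.nE = dims[0]; gs.nI = dims[1]; u_depth = dims[2];
    gs.e0 = as<double>(ctrl["e_min"]); gs.de = as<double>(ctrl["de"]);
    gs.i0 = as<double>(ctrl["i_min"]); gs.di = as<double>(ctrl["di"]);
  }

  NumericVector Eout(n_steps + 1);
  NumericVector Iout(store_I ? (n_steps + 1) : 0);
  std::vector<int> stim_steps;
  std::vector<double> stim_mags;
  std::vector<int> crossings;

  PhaseTracker tracker(bootstrap_steps > 0 ? bootstrap_steps : 1);
  // running-mean centering buffer (previous cwin samples of E)
  std::vector<double> cbuf;
  double csum = 0.0;
  long cfill = 0, cpos = 0;
  if (cwin > 0) cbuf.assign(cwin, 0.0);

  double E = x0[0], I = x0[1];
  long last_stim = -(Nlim > 0 ? Nlim : 1);
  double dEdt, dIdt;

  for (long i = 0; i <= n_steps; ++i) {
    // record observed (pre-pulse) sample
    Eout[i] = E;
    if (store_I) Iout[i] = I;

    bool pulse = false;
    if (mode == 1) {
      if (hf_interval > 0 && i > 0 && (i % hf_interval) == 0) pulse = true;
    } else if (mode == 2 || mode == 3) {
      double ref = (cfill >= cwin && cwin > 0) ? (csum / (double)cwin) : estar;
      double ec = E - ref;
      bool cross = tracker.update(ec, i);
      if (cross) crossings.push_back((int)i + 1);
      if (mode == 2) {
        if (cross) {
          bool missed = (tracker.ncross >= 2 && !tracker.stim_this_period);
          tracker.stim_this_period = false;
          // missed-phase fallback: stimulate right at the crossing
          if (missed) pulse = true;
        }
        if (!pulse && !tracker.stim_this_period &&
            tracker.phase >= target_phase && tracker.ncross >= 1)
          pulse = true;
      } else { // mode 3, Algorithm 2
        if (cross) tracker.stim_this_period = false;
        bool eligible = (i - last_stim >= Nlim) && !tracker.stim_this_period;
        if (eligible) {
          int pb = bin_index_1d(E, gs.e0, gs.de, gs.nE);
          int qb = bin_index_1d(I, gs.i0, gs.di, gs.nI);
          if (pb >= 0 && qb >= 0) {
            const double* g = gamma + pb + (R_xlen_t)gs.nE * qb;
            R_xlen_t stride = (R_xlen_t)gs.nE * gs.nI;
            if (algo2_core(g, stride, u_depth, i, tracker.n0, tracker.n1,
                           b_disc, dt))
              pulse = true;
          }
        }
      }
      // centering buffer holds the observed samples (pre-pulse)
      if (cwin > 0) {
        if (cfill < cwin) {
          cbuf[cpos] = E; csum += E; ++cfill;
        } else {
          csum += E - cbuf[cpos]; cbuf[cpos] = E;
        }
        cpos = (cpos + 1) % cwin;
      }
    }

    if (pulse) {
      E += dE_pulse;                     // stimulation vector (dE, 0)
      stim_steps.push_back((int)i + 1);  // 1-based grid index
      stim_mags.push_back(dE_pulse);
      last_stim = i;
      tracker.stim_this_period = true;
    }

    if (i == n_steps) break;
    wc_drift(p, E, I, dEdt, dIdt);
    E += dEdt * dt;
    I += dIdt * dt;
    if (sig > 0.0) {
      E += sig * norm_rand();
      I += sig * norm_rand();
    }
    if (!std::isfinite(E) || !std::isfinite(I))
      stop("non-finite state at step %ld", i + 1);
    if ((i % 100000) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["E"] = Eout, _["I"] = Iout,
                      _["stim_steps"] = wrap(stim_steps),
                      _["stim_magnitudes"] = wrap(stim_mags),
                      _["crossings"] = wrap(crossings));
}

// ---------------------------------------------------------------------------
// response-field machinery (Algorithm 1)
// ---------------------------------------------------------------------------

// deterministic Euler trajectories from every bin center over u steps,
// returned as 0-based bin indices (-1 when outside the grid)
// [[Rcpp::export]]
List cpp_bin_trajectories(NumericVector pv, double e_min, double de, int nE,
                          double i_min, double di, int nI,
                          double dt, int u) {
  WCParams p = unpack(pv);
  R_xlen_t nb = (R_xlen_t)nE * nI;
  IntegerMatrix P(nb, u), Q(nb, u);
  double dEdt, dIdt;
  for (int j = 0; j < nI; ++j) {
    for (int i = 0; i < nE; ++i) {
      R_xlen_t bin = i + (R_xlen_t)nE * j;
      double E = e_min + (i + 0.5) * de;
      double I = i_min + (j + 0.5) * di;
      for (int k = 0; k < u; ++k) {
        P(bin, k) = bin_index_1d(E, e_min, de, nE);
        Q(bin, k) = bin_index_1d(I, i_min, di, nI);
        if (k == u - 1) break;
        wc_drift(p, E, I, dEdt, dIdt);
        E += dEdt * dt;
        I += dIdt * dt;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["p"] = P, _["q"] = Q);
}

// Algorithm 1 update rule: Gamma(i,j,k) = Gamma0(p,q) when Gamma0(p,q) < 0
// and Gamma0(p,q) <= Gamma0(i,j), else 0.  Out-of-grid steps contribute 0.
// [[Rcpp::export]]
NumericVector cpp_algo1(NumericMatrix gamma0, IntegerMatrix P,
                        IntegerMatrix Q) {
  int nE = gamma0.nrow(), nI = gamma0.ncol();
  int u = P.ncol();
  R_xlen_t nb = (R_xlen_t)nE * nI;
  NumericVector G((R_xlen_t)nb * u);
  G.attr("dim") = IntegerVector::create(nE, nI, u);
  for (R_xlen_t bin = 0; bin < nb; ++bin) {
    double own = gamma0[bin];
    for (int k = 0; k < u; ++k) {
      int pi = P(bin, k), qi = Q(bin, k);
      double val = 0.0;
      if (pi >= 0 && qi >= 0) {
        double g = gamma0(pi, qi);
        if (g < 0.0 && g <= own) val = g;
      }
      G[bin + nb * k] = val;
    }
  }
  return G;
}

// ---------------------------------------------------------------------------
// field accumulation helper (Hilbert fields)
// ---------------------------------------------------------------------------

// adds amplitude samples into per-bin sums/counts (modified in place)
// [[Rcpp::export]]
void cpp_bin_accumulate(NumericVector E, NumericVector I, NumericVector amp,
                        double e_min, double de, int nE,
                        double i_min, double di, int nI,
                        NumericVector sums, IntegerVector counts) {
  R_xlen_t n = E.size();
  for (R_xlen_t s = 0; s < n; ++s) {
    int i = bin_index_1d(E[s], e_min, de, nE);
    int j = bin_index_1d(I[s], i_min, di, nI);
    if (i < 0 || j < 0) continue;
    R_xlen_t bin = i + (R_xlen_t)nE * j;
    sums[bin] += amp[s];
    counts[bin] += 1;
  }
}
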