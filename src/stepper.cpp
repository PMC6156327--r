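#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Integer power; 0^0 = 1 so Hill derivatives with n = 1 behave at x = 0.
static inline double powi(double x, int n) {
  double r = 1.0;
  while (n) { if (n & 1) r *= x; x *= x; n >>= 1; }
  return r;
}

struct Model {
  double a, b, c, k1, k2, theta;
  int n1, n2, n3;
  double th1, th2, th3;
};

// par: a b c k1 k2 n1 n2 n3 theta
static Model make_model(const NumericVector& par) {
  Model m;
  m.a = par[0]; m.b = par[1]; m.c = par[2];
  m.k1 = par[3]; m.k2 = par[4];
  m.n1 = (int)par[5]; m.n2 = (int)par[6]; m.n3 = (int)par[7];
  m.theta = par[8];
  m.th1 = powi(m.theta, m.n1);
  m.th2 = powi(m.theta, m.n2);
  m.th3 = powi(m.theta, m.n3);
  return m;
}

// ZEB production: self-activation (argument may be delayed) + miR-200 repression.
static inline double prod1(const Model& m, double x1act, double x2) {
  double h1 = powi(x1act, m.n1);
  double h2 = powi(x2, m.n2);
  return m.a * h1 / (m.th1 + h1) + m.c * m.th2 / (m.th2 + h2);
}

static inline double drift2(const Model& m, double x1, double x2) {
  double h3 = powi(x1, m.n3);
  return m.b * m.th3 / (m.th3 + h3) - m.k2 * x2;
}

// Euler(-Maruyama) stepper with optional discrete delay in the self-activation
// term. Reflecting boundary at 0 in both coordinates. Uses R's RNG so that
// set.seed() in R gives bit-identical trajectories.
// Returns (floor(nsteps/thin)+1) x 2 matrix of states, row 0 = initial state.
// [[Rcpp::export]]
NumericMatrix sim_path_cpp(NumericVector par, NumericVector x0, double dt,
                           int nsteps, double D, int thin, int tau_steps) {
  Model m = make_model(par);
  double x1 = x0[0], x2 = x0[1];
  double s = (D > 0) ? std::sqrt(2.0 * D * dt) : 0.0;
  // sanity box: drift is inward beyond (a+c)/k1 x b/k2; 10x that flags dt trouble
  double cap1 = 10.0 * std::max(1.0, (m.a + m.c) / m.k1);
  double cap2 = 10.0 * std::max(1.0, m.b / m.k2);
  int nrec = nsteps / thin + 1;
  NumericMatrix out(nrec, 2);
  out(0, 0) = x1; out(0, 1) = x2;
  std::vector<double> hist;
  int hpos = 0;
  if (tau_steps > 0) hist.assign(tau_steps, x1); // constant pre-history
  int rec = 1;
  for (int step = 1; step <= nsteps; ++step) {
    double x1act = x1;
    if (tau_steps > 0) x1act = hist[hpos];
    double f1 = prod1(m, x1act, x2) - m.k1 * x1;
    double f2 = drift2(m, x1, x2);
    double z1 = 0.0, z2 = 0.0;
    if (D > 0) { z1 = norm_rand(); z2 = norm_rand(); }
    double nx1 = x1 + f1 * dt + s * z1;
    double nx2 = x2 + f2 * dt + s * z2;
    if (nx1 < 0) nx1 = -nx1;
    if (nx2 < 0) nx2 = -nx2;
    if (tau_steps > 0) { hist[hpos] = x1; hpos = (hpos + 1) % tau_steps; }
    x1 = nx1; x2 = nx2;
    if (x1 > cap1 || x2 > cap2 || !R_finite(x1) || !R_finite(x2))
      stop("trajectory left the sanity box at t = %g; decrease dt", step * dt);
    if (step % thin == 0 && rec < nrec) {
      out(rec, 0) = x1; out(rec, 1) = x2; ++rec;
    }
  }
  return out;
}

// Accumulates a 2-D occupancy histogram over an ensemble of chains without
// storing samples. Every post-burn-in step of every chain contributes one
// count. States beyond the grid edge are clamped into the outermost bin.
// [[Rcpp::export]]
NumericMatrix sim_hist_cpp(NumericVector par, NumericMatrix starts, double dt,
                           int nsteps, int burn_steps, double D,
                           double x1max, int nx, double x2max, int ny) {
  Model m = make_model(par);
  double s = (D > 0) ? std::sqrt(2.0 * D * dt) : 0.0;
  double cap1 = 10.0 * std::max(1.0, (m.a + m.c) / m.k1);
  double cap2 = 10.0 * std::max(1.0, m.b / m.k2);
  NumericMatrix counts(nx, ny);
  double sx = nx / x1max, sy = ny / x2max;
  for (int ch = 0; ch < starts.nrow(); ++ch) {
    double x1 = starts(ch, 0), x2 = starts(ch, 1);
    for (int step = 1; step <= nsteps; ++step) {
      double f1 = prod1(m, x1, x2) - m.k1 * x1;
      double f2 = drift2(m, x1, x2);
      double z1 = 0.0, z2 = 0.0;
      if (D > 0) { z1 = norm_rand(); z2 = norm_rand(); }
      x1 += f1 * dt + s * z1;
      x2 += f2 * dt + s * z2;
      if (x1 < 0) x1 = -x1;
      if (x2 < 0) x2 = -x2;
      if (x1 > cap1 || x2 > cap2 || !R_finite(x1) || !R_finite(x2))
        stop("trajectory left the sanity box at t = %g; decrease dt", step * dt);
      if (step > burn_steps) {
        int i = (int)(x1 * sx); if (i >= nx) i = nx - 1;
        int j = (int)(x2 * sy); if (j >= ny) j = ny - 1;
        counts(i, j) += 1.0;
      }
    }
  }
  return counts;
}

// Batch first-passage sampler: ntraj trajectories started at x0, stopped on
// first entry into the capture set around `target`. capture_mode 0: euclidean
// ball of `radius`; 1: |x1 - target_x1| <= radius (1-D reduction check).
// Censored trajectories (t > tmax) return NA.
// [[Rcpp::export]]
NumericVector sim_fpt_cpp(NumericVector par, NumericVector x0,
                          NumericVector target, double radius, double dt,
                          double D, double tmax, int ntraj, int capture_mode) {
  Model m = make_model(par);
  double s = std::sqrt(2.0 * D * dt);
  double cap1 = 10.0 * std::max(1.0, (m.a + m.c) / m.k1);
  double cap2 = 10.0 * std::max(1.0, m.b / m.k2);
  double r2 = radius * radius;
  long maxsteps = (long)(tmax / dt);
  NumericVector out(ntraj);
  for (int k = 0; k < ntraj; ++k) {
    double x1 = x0[0], x2 = x0[1];
    double t = NA_REAL;
    for (long step = 1; step <= maxsteps; ++step) {
      double f1 = prod1(m, x1, x2) - m.k1 * x1;
      double f2 = drift2(m, x1, x2);
      x1 += f1 * dt + s * norm_rand();
      x2 += f2 * dt + s * norm_rand();
      if (x1 < 0) x1 = -x1;
      if (x2 < 0) x2 = -x2;
      if (x1 > cap1 || x2 > cap2 || !R_finite(x1) || !R_finite(x2))
        stop("trajectory left the sanity box; decrease dt");
      bool hit;
      if (capture_mode == 1) {
        hit = std::abs(x1 - target[0]) <= radius;
      } else {
        double d1 = x1 - target[0], d2 = x2 - target[1];
        hit = d1 * d1 + d2 * d2 <= r2;
      }
      if (hit) { t = step * dt; break; }
    }
    out[k] = t;
    if (k % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
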