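#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// plr thresholding operator: soft (kap = 0), firm/MCP (0 < kap < 1),
// hard (kap = 1), elastic-net (kap < 0: soft threshold then proportional
// shrinkage by 1/(1 - kap)).
// ---------------------------------------------------------------------------
static inline double plr1(double x, double lam, double kap) {
  double ax = std::fabs(x);
  if (kap >= 1.0) return (ax < lam) ? 0.0 : x;      // hard-threshold limit
  if (ax < lam) return 0.0;                          // dead zone
  if (kap > 0.0 && ax >= lam / kap) return x;        // unshrunk MCP region
  double s = (x > 0.0) ? 1.0 : -1.0;
  return (x - lam * s) / (1.0 - kap);
}

// [[Rcpp::export]]
NumericVector plr_threshold_cpp(NumericVector x, double lam, double kap) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = plr1(x[i], lam, kap);
  return out;
}

static inline double plogis1(double e) { return 1.0 / (1.0 + std::exp(-e)); }

// ---------------------------------------------------------------------------
// Cyclic coordinate descent on the quadratic majorization of the logistic
// log-likelihood (curvature bound 1/4).  X must be column-standardized
// (mean 0, population sd 1), so each coordinate's majorizer curvature is
// w = n/4 and the per-coordinate standard error on the standardized scale
// is se = 2/sqrt(n); the penalty lam is applied on the z = beta/se scale.
// Coefficients enter/leave the model through plr1; intercept unpenalized.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cd_fit_cpp(NumericMatrix X, NumericVector y, double lam, double kap,
                NumericVector beta0, double intercept0,
                double tol, int max_iter) {
  int n = X.nrow(), m = X.ncol();
  double w = n / 4.0;
  double se = 2.0 / std::sqrt((double)n);

  NumericVector beta = clone(beta0);
  double b0 = intercept0;
  std::vector<double> eta(n), p(n);
  for (int i = 0; i < n; ++i) eta[i] = b0;
  for (int j = 0; j < m; ++j) {
    if (beta[j] != 0.0) {
      double bj = beta[j];
      for (int i = 0; i < n; ++i) eta[i] += X(i, j) * bj;
    }
  }
  for (int i = 0; i < n; ++i) p[i] = plogis1(eta[i]);

  std::vector<int> active;
  bool converged = false;
  int sweep = 0;

  auto update_coord = [&](int j) -> double {
    double g = 0.0;
    for (int i = 0; i < n; ++i) g += X(i, j) * (y[i] - p[i]);
    double z = beta[j] + g / w;
    double bnew = se * plr1(z / se, lam, kap);
    double d = bnew - beta[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) {
        eta[i] += X(i, j) * d;
        p[i] = plogis1(eta[i]);
      }
      beta[j] = bnew;
    }
    return std::fabs(d);
  };
  auto update_intercept = [&]() -> double {
    double g = 0.0;
    for (int i = 0; i < n; ++i) g += y[i] - p[i];
    double d = g / w;  // majorized Newton step, curvature n/4
    if (d != 0.0) {
      b0 += d;
      for (int i = 0; i < n; ++i) {
        eta[i] += d;
        p[i] = plogis1(eta[i]);
      }
    }
    return std::fabs(d);
  };

  while (sweep < max_iter) {
    // full sweep
    ++sweep;
    double maxd = update_intercept();
    for (int j = 0; j < m; ++j) {
      double d = update_coord(j);
      if (d > maxd) maxd = d;
    }
    if (maxd < tol) { converged = true; break; }
    // active-set sweeps
    active.clear();
    for (int j = 0; j < m; ++j) if (beta[j] != 0.0) active.push_back(j);
    while (sweep < max_iter) {
      ++sweep;
      double amaxd = update_intercept();
      for (size_t k = 0; k < active.size(); ++k) {
        double d = update_coord(active[k]);
        if (d > amaxd) amaxd = d;
      }
      if (amaxd < tol) break;
    }
  }

  IntegerVector act;
  for (int j = 0; j < m; ++j) if (beta[j] != 0.0) act.push_back(j + 1);
  return List::create(_["beta"] = beta, _["intercept"] = b0,
                      _["active"] = act, _["converged"] = converged,
                      _["n_iter"] = sweep);
}

// ---------------------------------------------------------------------------
// Generalized inverse Gaussian sampler, GIG(p, a, b) with density
// proportional to x^(p-1) exp(-(a x + b / x) / 2), following Devroye's
// rejection construction for the two-parameter form.  Uses R's RNG so
// draws are reproducible under set.seed().
// ---------------------------------------------------------------------------
static inline double gig_psi(double x, double alpha, double lam) {
  return -alpha * (std::cosh(x) - 1.0) - lam * (std::exp(x) - x - 1.0);
}
static inline double gig_dpsi(double x, double alpha, double lam) {
  return -alpha * std::sinh(x) - lam * (std::exp(x) - 1.0);
}

static double gigrnd1(double pp, double a, double b) {
  double lam = pp;
  bool swap = false;
  if (lam < 0.0) { lam = -lam; swap = true; }
  double omega = std::sqrt(a * b);
  double alpha = std::sqrt(omega * omega + lam * lam) - lam;

  // envelope knots t and s
  double x = -gig_psi(1.0, alpha, lam), t, s;
  if (x >= 0.5 && x <= 2.0) t = 1.0;
  else if (x > 2.0) t = std::sqrt(2.0 / (alpha + lam));
  else t = std::log(4.0 / (alpha + 2.0 * lam));

  x = -gig_psi(-1.0, alpha, lam);
  if (x >= 0.5 && x <= 2.0) s = 1.0;
  else if (x > 2.0) s = std::sqrt(4.0 / (alpha * std::cosh(1.0) + lam));
  else {
    double s1 = std::log(1.0 + 1.0 / alpha +
                         std::sqrt(1.0 / (alpha * alpha) + 2.0 / alpha));
    s = (lam > 0.0) ? std::min(1.0 / lam, s1) : s1;
  }

  double eta = -gig_psi(t, alpha, lam);
  double zeta = -gig_dpsi(t, alpha, lam);
  double theta = -gig_psi(-s, alpha, lam);
  double xi = gig_dpsi(-s, alpha, lam);
  double pq = 1.0 / xi, r = 1.0 / zeta;
  double td = t - r * eta, sd = s - pq * theta;
  double q = td + sd;

  double rnd = 0.0;
  for (int it = 0; it < 10000; ++it) {
    double U = unif_rand(), V = unif_rand(), W = unif_rand();
    if (U < q / (pq + q + r)) rnd = -sd + q * V;
    else if (U < (q + r) / (pq + q + r)) rnd = td - r * std::log(V);
    else rnd = -sd + pq * std::log(V);
    double f1 = std::exp(-eta - zeta * (rnd - t));
    double f2 = std::exp(-theta + xi * (rnd + s));
    double gg;
    if (rnd >= -sd && rnd <= td) gg = 1.0;
    else if (rnd > td) gg = f1;
    else gg = f2;
    if (W * gg <= std::exp(gig_psi(rnd, alpha, lam))) break;
  }
  rnd = std::exp(rnd) *
        (lam / omega + std::sqrt(1.0 + (lam * lam) / (omega * omega)));
  if (swap) rnd = 1.0 / rnd;
  return rnd / std::sqrt(a / b);
}

// [[Rcpp::export]]
NumericVector rgig_cpp(double p, NumericVector a, NumericVector b) {
  int n = a.size();
  NumericVector out(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double ai = std::max(a[i], 1e-12), bi = std::max(b[i], 1e-12);
    out[i] = gigrnd1(p, ai, bi);
  }
  return out;
}
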