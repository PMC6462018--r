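#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
#include <random>
using namespace Rcpp;

// Two-component, equal-variance, univariate Gaussian mixture fitted by EM.
//
// Model: f(x) = pi * N(x; mu_low, sigma^2) + (1 - pi) * N(x; mu_high, sigma^2),
// pi the mixing weight of the LOW component. The E-step uses the logistic form
// of the responsibility (one exp() per observation), which is what makes the
// half-million fits of a null-score calibration run tractable.

namespace {

struct FitResult {
  double pi, mu_low, mu_high, sigma, loglik;
  int n_iter;
  bool converged;      // tolerance met and sigma never floored
  bool hit_floor;
};

const double LOG_2PI = 1.8378770664093454836;

// One EM run from a given split-quantile initialisation.
FitResult em_run(const std::vector<double>& x, double split_q,
                 double tol, int max_iter, double sigma_floor,
                 std::vector<double>* trace) {
  const int n = (int)x.size();
  std::vector<double> xs(x);
  std::sort(xs.begin(), xs.end());

  // initial parameters: means of the two halves of the sorted data,
  // pooled within-half SD, pi = split fraction
  int k = (int)std::floor(split_q * n);
  if (k < 1) k = 1;
  if (k > n - 1) k = n - 1;
  double s1 = 0.0, s2 = 0.0;
  for (int i = 0; i < k; ++i) s1 += xs[i];
  for (int i = k; i < n; ++i) s2 += xs[i];
  double mu1 = s1 / k, mu2 = s2 / (n - k);
  double ss = 0.0;
  for (int i = 0; i < k; ++i) ss += (xs[i] - mu1) * (xs[i] - mu1);
  for (int i = k; i < n; ++i) ss += (xs[i] - mu2) * (xs[i] - mu2);
  double sigma = std::sqrt(ss / n);
  if (!(sigma > 0.0)) {
    // halves internally constant; fall back to overall SD
    double m = (s1 + s2) / n, tot = 0.0;
    for (int i = 0; i < n; ++i) tot += (x[i] - m) * (x[i] - m);
    sigma = std::sqrt(tot / n);
    if (!(sigma > 0.0)) sigma = sigma_floor;
  }
  double pi = (double)k / n;

  std::vector<double> r(n);
  double loglik = -std::numeric_limits<double>::infinity();
  double ll_prev2 = -std::numeric_limits<double>::infinity();
  bool hit_floor = false, converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // E-step + observed-data log-likelihood. With equal variances the
    // log-odds of LOW vs HIGH membership is linear in x: eta = a + b*x,
    // so one exp() per observation suffices.
    const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    const double a = std::log(pi / (1.0 - pi)) + (mu2 * mu2 - mu1 * mu1) * inv2s2;
    const double b = -2.0 * (mu2 - mu1) * inv2s2;
    const double log1mpi = std::log1p(-pi);
    double ll = 0.0;
    double sr = 0.0, srx = 0.0, meanx = 0.0;
    for (int i = 0; i < n; ++i) {
      double eta = a + b * x[i];
      double e = std::exp(-std::fabs(eta)); // in (0,1]
      double ri = (eta >= 0) ? 1.0 / (1.0 + e) : e / (1.0 + e);
      // log(pi phi1 + (1-pi) phi2) = max(t1,t2) + log1p(e), t1 - t2 = eta
      double z2 = x[i] - mu2;
      double t2 = log1mpi - z2 * z2 * inv2s2;
      ll += (eta >= 0 ? t2 + eta : t2) + std::log1p(e);
      r[i] = ri;
      sr += ri;
      srx += ri * x[i];
      meanx += x[i];
    }
    ll += -n * (0.5 * LOG_2PI + std::log(sigma));
    if (trace) trace->push_back(ll);

    // Convergence: plain change below tol, or the Aitken-extrapolated
    // log-likelihood limit within tol of the current value. EM creeps
    // sublinearly on near-unimodal data; the Aitken criterion recognises a
    // converged run long before the raw increments shrink below tol.
    double d1 = ll - loglik;            // current increment
    if (std::fabs(d1) < tol) { loglik = ll; converged = true; break; }
    if (iter >= 3 && ll_prev2 > -std::numeric_limits<double>::infinity()) {
      double d0 = loglik - ll_prev2;    // previous increment
      if (d0 > 0.0 && d1 > 0.0) {
        double a = d1 / d0;
        if (a > 0.0 && a < 1.0) {
          double ll_inf = loglik + d1 / (1.0 - a);
          if (std::fabs(ll_inf - ll) < tol) {
            loglik = ll; converged = true; break;
          }
        }
      }
    }
    ll_prev2 = loglik;
    loglik = ll;

    // M-step (uses the stored E-step responsibilities)
    double pin = sr / n;
    if (pin < 1e-12) pin = 1e-12;
    if (pin > 1.0 - 1e-12) pin = 1.0 - 1e-12;
    double m1 = srx / std::max(sr, 1e-300);
    double m2 = (meanx - srx) / std::max((double)n - sr, 1e-300);
    double ssn = 0.0;
    for (int i = 0; i < n; ++i) {
      double d1 = x[i] - m1, d2 = x[i] - m2;
      ssn += r[i] * d1 * d1 + (1.0 - r[i]) * d2 * d2;
    }
    double sn = std::sqrt(ssn / n);
    if (sn < sigma_floor) { sn = sigma_floor; hit_floor = true; }
    pi = pin; mu1 = m1; mu2 = m2; sigma = sn;
  }
  if (iter > max_iter) iter = max_iter;

  FitResult res;
  // enforce mu_low <= mu_high
  if (mu1 <= mu2) { res.pi = pi; res.mu_low = mu1; res.mu_high = mu2; }
  else { res.pi = 1.0 - pi; res.mu_low = mu2; res.mu_high = mu1; }
  res.sigma = sigma;
  res.loglik = loglik;
  res.n_iter = iter;
  res.hit_floor = hit_floor;
  res.converged = converged && !hit_floor;
  return res;
}

// uniforms in (0,1) from a seeded mt19937, avoiding distribution objects
// (their output is implementation-defined)
inline double mt_unif(std::mt19937& gen) {
  return (gen() + 0.5) / 4294967296.0;
}

// Best of `restarts` EM runs by log-likelihood. The convergence flag is an
// any-run property: the fit counts as converged when at least one restart met
// the tolerance (the runs meet in the same basin; a slow-creeping best run
// differs from a converged one by a negligible likelihood margin), but a
// selected run that collapsed onto the variance floor is never converged.
FitResult fit_one(const std::vector<double>& x, unsigned int seed,
                  int restarts, double tol, int max_iter, double sigma_floor,
                  std::vector<double>* trace_best) {
  std::mt19937 gen(seed);
  FitResult best;
  best.loglik = -std::numeric_limits<double>::infinity();
  bool any_tol = false;
  std::vector<double> trace_cur;
  for (int r = 0; r < restarts; ++r) {
    double q = (r == 0) ? 0.5 : 0.2 + 0.6 * mt_unif(gen);
    std::vector<double>* tp = trace_best ? &trace_cur : nullptr;
    if (tp) tp->clear();
    FitResult f = em_run(x, q, tol, max_iter, sigma_floor, tp);
    if (f.converged) any_tol = true;
    if (f.loglik > best.loglik ||
        (r == 0 && !std::isfinite(best.loglik))) {
      best = f;
      if (trace_best) *trace_best = trace_cur;
    }
  }
  best.converged = any_tol && !best.hit_floor;
  return best;
}

} // namespace

// [[Rcpp::export(name = ".gmm_em_fit")]]
List gmm_em_fit(NumericVector x, int seed, int restarts, double tol,
                int max_iter, double sigma_floor, bool trace) {
  int n = x.size();
  if (n < 4) stop("at least 4 observations are required (got %d)", n);
  std::vector<double> v(n);
  double mn = R_PosInf, mx = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (!R_finite(x[i])) stop("non-finite value at position %d", i + 1);
    v[i] = x[i];
    mn = std::min(mn, v[i]); mx = std::max(mx, v[i]);
  }
  if (mx - mn <= 0.0)
    stop("all values are identical; mixture standard deviation would collapse");
  std::vector<double> tr;
  FitResult f = fit_one(v, (unsigned int)seed, restarts, tol, max_iter,
                        sigma_floor, trace ? &tr : nullptr);
  List out = List::create(
    _["pi"] = f.pi, _["mu_low"] = f.mu_low, _["mu_high"] = f.mu_high,
    _["sigma"] = f.sigma, _["log_lik"] = f.loglik,
    _["converged"] = f.converged, _["n_iter"] = f.n_iter);
  if (trace) out["trace"] = NumericVector(tr.begin(), tr.end());
  return out;
}

// Fit every row of a genes x samples matrix with per-row restart seeds.
// [[Rcpp::export(name = ".gmm_em_fit_rows")]]
NumericMatrix gmm_em_fit_rows(NumericMatrix X, IntegerVector seeds, int restarts,
                              double tol, int max_iter, double sigma_floor) {
  int g = X.nrow(), n = X.ncol();
  if (n < 4) stop("at least 4 samples are required per gene");
  if (seeds.size() != g) stop("`seeds` must have one entry per row");
  NumericMatrix out(g, 7);
  colnames(out) = CharacterVector::create("pi", "mu_low", "mu_high", "sigma",
                                          "log_lik", "converged", "n_iter");
  std::vector<double> v(n);
  for (int i = 0; i < g; ++i) {
    double mn = R_PosInf, mx = R_NegInf;
    bool ok = true;
    for (int j = 0; j < n; ++j) {
      double val = X(i, j);
      if (!R_finite(val)) { ok = false; break; }
      v[j] = val;
      mn = std::min(mn, val); mx = std::max(mx, val);
    }
    if (!ok || mx - mn <= 0.0) {
      for (int c = 0; c < 7; ++c) out(i, c) = NA_REAL;
      out(i, 5) = 0.0;
      continue;
    }
    FitResult f = fit_one(v, (unsigned int)seeds[i], restarts, tol,
                          max_iter, sigma_floor, nullptr);
    out(i, 0) = f.pi; out(i, 1) = f.mu_low; out(i, 2) = f.mu_high;
    out(i, 3) = f.sigma; out(i, 4) = f.loglik;
    out(i, 5) = f.converged ? 1.0 : 0.0; out(i, 6) = f.n_iter;
  }
  return out;
}
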