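// Wiener first-passage-time kernel: density (small-time / large-time series),
// summed log-likelihood, and an Euler path simulator with Brownian-bridge
// boundary-crossing correction. Diffusion coefficient fixed at 1.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// First-passage density at the LOWER boundary of a driftless unit-diffusion
// process with boundary separation 1 and relative start w, at normalised
// time tt = t / a^2. Series truncation follows the standard error bound at
// tolerance eps; the expansion with the fewer required terms is used.
// method: 0 = automatic switch, 1 = force small-time, 2 = force large-time.
static double fpt_std(double tt, double w, double eps, int method) {
  if (tt <= 0.0 || !std::isfinite(tt)) return 0.0;

  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tt)));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tt * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }

  bool use_small = (method == 1) || (method == 0 && ks < kl);
  double p = 0.0;
  if (use_small) {
    int K = (int) std::ceil(ks);
    int lo = -(int) std::floor((K - 1) / 2.0);
    int hi = (int) std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; ++k) {
      double x = w + 2.0 * k;
      p += x * std::exp(-x * x / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {
    int K = (int) std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
           std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p > 0.0 ? p : 0.0;
}

// Density of first passage at the lower boundary at clock time t, for drift
// v, boundary separation a, relative start z, non-decision time t0.
static double wfpt_lower(double t, double v, double a, double z, double t0,
                         double eps, int method) {
  double tu = t - t0;
  if (tu <= 0.0) return 0.0;
  double tt = tu / (a * a);
  double p = fpt_std(tt, z, eps, method);
  if (p <= 0.0) return 0.0;
  return p * std::exp(-v * a * z - v * v * tu / 2.0) / (a * a);
}

// [[Rcpp::export]]
NumericVector wfpt_cpp(NumericVector t, IntegerVector upper, NumericVector v,
                       NumericVector a, NumericVector z, NumericVector t0,
                       double eps, int method) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double vi = v[i], zi = z[i];
    if (upper[i] == 1) { // upper-boundary density via reflection
      vi = -vi;
      zi = 1.0 - zi;
    }
    out[i] = wfpt_lower(t[i], vi, a[i], zi, t0[i], eps, method);
  }
  return out;
}

// Summed log density for one subject: scalar v, a, t0; z per trial (length 1
// or n). Trials with rt <= t0 contribute -Inf.
// [[Rcpp::export]]
double wfpt_loglik_cpp(NumericVector rt, IntegerVector upper, double v,
                       double a, NumericVector z, double t0, double eps) {
  int n = rt.size();
  bool zscalar = (z.size() == 1);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double zi = zscalar ? z[0] : z[i];
    double vi = v;
    if (upper[i] == 1) {
      vi = -vi;
      zi = 1.0 - zi;
    }
    double d = wfpt_lower(rt[i], vi, a, zi, t0, eps, 0);
    if (d <= 0.0) return R_NegInf;
    ll += std::log(d);
  }
  return ll;
}

// Euler-Maruyama simulation of the two-boundary Wiener process, with the
// Brownian-bridge crossing probability applied within each step so the
// discretisation bias is O(dt) rather than O(sqrt(dt)). Returns first-passage
// clock times (t0 added) and the boundary hit (1 = upper, 0 = lower).
// [[Rcpp::export]]
List wiener_sim_cpp(int n, double v, double a, double z, double t0,
                    double dt) {
  NumericVector rt(n);
  IntegerVector boundary(n);
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = z * a, t = 0.0;
    int b = -1;
    while (b < 0) {
      double xn = x + v * dt + sdt * norm_rand();
      t += dt;
      if (xn >= a) {
        b = 1;
      } else if (xn <= 0.0) {
        b = 0;
      } else {
        double pu = std::exp(-2.0 * (a - x) * (a - xn) / dt);
        if (unif_rand() < pu) {
          b = 1;
        } else {
          double pl = std::exp(-2.0 * x * xn / dt);
          if (unif_rand() < pl) b = 0;
        }
      }
      if (b < 0) {
        x = xn;
        if (t > 600.0) { // pathological parameter guard; restart the path
          x = z * a;
          t = 0.0;
        }
      }
    }
    rt[i] = t0 + t;
    boundary[i] = b;
  }
  return List::create(_["rt"] = rt, _["boundary"] = boundary);
}
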