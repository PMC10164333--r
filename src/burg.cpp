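// Burg autoregressive fitting and adaptive band-power integration.
// Hot path of the ERD decoder: one call per 500 ms analysis window.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <complex>
#include <algorithm>
using namespace Rcpp;

// Burg recursion, matching stats::ar.burg(demean = TRUE, var.method = 1):
// coefficients a_k such that x_t = sum_k a_k x_{t-k} + e_t, innovation
// variance estimated from the final forward/backward prediction errors.
// [[Rcpp::export(name = ".burg_fit_cpp")]]
List burg_fit_cpp(NumericVector x, int order) {
  int n = x.size();
  std::vector<double> f(n), b(n);
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  for (int i = 0; i < n; ++i) f[i] = b[i] = x[i] - mean;
  std::vector<double> a(order, 0.0), a_prev(order, 0.0);
  double var = 0.0;
  for (int i = 0; i < n; ++i) var += f[i] * f[i];
  var /= n;
  for (int k = 1; k <= order; ++k) {
    double num = 0.0, den = 0.0;
    for (int i = k; i < n; ++i) {
      num += f[i] * b[i - 1];
      den += f[i] * f[i] + b[i - 1] * b[i - 1];
    }
    double refl = (den > 0.0) ? 2.0 * num / den : 0.0;
    a[k - 1] = refl;
    for (int i = 0; i < k - 1; ++i) a[i] = a_prev[i] - refl * a_prev[k - 2 - i];
    for (int i = 0; i < k; ++i) a_prev[i] = a[i];
    for (int i = n - 1; i >= k; --i) {
      double fi = f[i];
      f[i] = fi - refl * b[i - 1];
      b[i] = b[i - 1] - refl * fi;
    }
    var *= (1.0 - refl * refl);
  }
  // var.method = 1: mean of squared forward+backward residuals
  double vp = 0.0;
  for (int i = order; i < n; ++i) vp += f[i] * f[i] + b[i] * b[i];
  vp /= 2.0 * (n - order);
  return List::create(_["ar"] = NumericVector(a.begin(), a.end()),
                      _["var"] = vp, _["var_prod"] = var);
}

// one-sided AR PSD at frequency fr (Hz)
static inline double ar_psd(const std::vector<double>& a, double var,
                            double fs, double fr) {
  double w = 2.0 * M_PI * fr / fs;
  std::complex<double> A(1.0, 0.0);
  for (size_t k = 0; k < a.size(); ++k)
    A -= a[k] * std::complex<double>(std::cos(w * (k + 1)),
                                     -std::sin(w * (k + 1)));
  double denom = std::norm(A);
  if (denom <= 0.0) denom = 1e-300;
  return 2.0 * var / (fs * denom);
}

struct Seg { double lo, hi, ylo, yhi, err, fine; };

// Adaptive trapezoid over [lo, hi] from a coarse grid (grid_step Hz),
// bisecting the worst segments first with a bounded work budget; resolves
// the very narrow resonances of high-order AR spectra.
// [[Rcpp::export(name = ".ar_band_power_cpp")]]
double ar_band_power_cpp(NumericVector ar, double var, double fs,
                         double lo, double hi, double grid_step = 0.1,
                         double rtol = 1e-3, int max_sweeps = 60,
                         int max_active = 256) {
  std::vector<double> a(ar.begin(), ar.end());
  if (var <= 0.0) return 0.0;
  std::vector<Seg> act;
  int n0 = (int)std::ceil((hi - lo) / grid_step - 1e-9);
  if (n0 < 1) n0 = 1;
  double prev_f = lo, prev_y = ar_psd(a, var, fs, lo);
  for (int i = 1; i <= n0; ++i) {
    double f = (i == n0) ? hi : lo + i * grid_step;
    double y = ar_psd(a, var, fs, f);
    act.push_back({prev_f, f, prev_y, y, 0.0, 0.0});
    prev_f = f; prev_y = y;
  }
  double total = 0.0;
  for (int sweep = 0; sweep < max_sweeps && !act.empty(); ++sweep) {
    std::vector<Seg> next;
    std::vector<double> errs;
    for (auto& s : act) {
      double mid = 0.5 * (s.lo + s.hi);
      double ym = ar_psd(a, var, fs, mid);
      double h = s.hi - s.lo;
      double coarse = 0.5 * (s.ylo + s.yhi) * h;
      double fine = 0.25 * (s.ylo + 2.0 * ym + s.yhi) * h;
      double err = std::fabs(fine - coarse);
      if (err <= rtol * std::fabs(fine) + 1e-12 || h < 1e-12) {
        total += fine;
      } else {
        next.push_back({s.lo, mid, s.ylo, ym, err, fine});
        next.push_back({mid, s.hi, ym, s.yhi, err, fine});
        errs.push_back(err);
      }
    }
    if (next.empty()) return total;
    if ((int)next.size() > 2 * max_active) {
      std::sort(errs.begin(), errs.end(), std::greater<double>());
      double cut = errs[max_active - 1];
      std::vector<Seg> kept;
      for (auto& s : next) {
        if (s.err >= cut && (int)kept.size() < 2 * max_active)
          kept.push_back(s);
        else
          total += 0.5 * s.fine;  // parent's fine estimate, split in two
      }
      next.swap(kept);
    }
    act.swap(next);
  }
  for (auto& s : act) total += 0.5 * (s.ylo + s.yhi) * (s.hi - s.lo);
  return total;
}
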