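#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Template pair counts for sample entropy (Richman & Moorman convention:
// templates start at 1..N-m for both lengths m and m+1, self-matches excluded).
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const int nt = N - m;
  if (nt < 2) return List::create(_["A"] = 0.0, _["B"] = 0.0);
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int l = 0; l < m; ++l) {
        double t = std::fabs(x[i + l] - x[j + l]);
        if (t > d) d = t;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double t = std::fabs(x[i + m] - x[j + m]);
      double d1 = (t > d) ? t : d;
      if (d1 <= r) A += 1.0;
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}

// Fuzzy membership sums over mean-centered templates. Pairs whose Chebyshev
// distance exceeds cutoff_mult * r contribute exp(-(d/r)^grad) < exp(-cutoff^grad),
// numerically negligible; they are skipped (early abort) for speed.
// [[Rcpp::export]]
List fuzzyen_sums_cpp(NumericVector x, int m, double r, double grad,
                      double cutoff_mult = 8.0) {
  const int N = x.size();
  const int nt = N - m;
  if (nt < 2) return List::create(_["phi_m"] = NA_REAL, _["phi_m1"] = NA_REAL);
  const double cut = cutoff_mult * r;

  // centered templates, stored per lag so the pair loop is flat array math:
  // ym[l][i] = x[i+l] - mean(x[i..i+m-1]), yp[l][i] = x[i+l] - mean(x[i..i+m])
  std::vector<std::vector<double> > ym(m, std::vector<double>(nt));
  std::vector<std::vector<double> > yp(m + 1, std::vector<double>(nt));
  {
    double s = 0.0;
    for (int l = 0; l < m; ++l) s += x[l];
    for (int i = 0; i < nt; ++i) {
      double mu = s / m;
      double mu1 = (s + x[i + m]) / (m + 1);
      for (int l = 0; l < m; ++l) ym[l][i] = x[i + l] - mu;
      for (int l = 0; l <= m; ++l) yp[l][i] = x[i + l] - mu1;
      if (i + 1 < nt) s += x[i + m] - x[i];
    }
  }

  const double inv_r = 1.0 / r;
  const bool quad = (grad == 2.0);
  double sum_m = 0.0, sum_m1 = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      // length-m centered templates
      double d = 0.0;
      for (int l = 0; l < m; ++l) {
        double t = std::fabs(ym[l][i] - ym[l][j]);
        if (t > d) d = t;
      }
      if (d <= cut) {
        double t = d * inv_r;
        sum_m += quad ? std::exp(-t * t) : std::exp(-std::pow(t, grad));
      }
      // length-(m+1) centered templates (different centering)
      double d1 = 0.0;
      for (int l = 0; l <= m; ++l) {
        double t = std::fabs(yp[l][i] - yp[l][j]);
        if (t > d1) d1 = t;
      }
      if (d1 <= cut) {
        double t = d1 * inv_r;
        sum_m1 += quad ? std::exp(-t * t) : std::exp(-std::pow(t, grad));
      }
    }
  }
  const double np = 0.5 * nt * (nt - 1);
  return List::create(_["phi_m"] = sum_m / np, _["phi_m1"] = sum_m1 / np);
}

// LZ76 phrase count (Kaspar-Schuster algorithm) on an integer symbol sequence.
// [[Rcpp::export]]
int lz76_count_cpp(IntegerVector s) {
  const int n = s.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
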