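#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-counting kernels for approximate and sample entropy.
// Chebyshev (max-abs) distance between length-m templates.

// Count, for each template start i, the number of starts j with
// d(x_i, x_j) <= r over templates of length m. include_self controls
// whether j == i is counted (approximate entropy) or not (sample entropy).
static double phi_apen(const NumericVector& x, int m, double r) {
  int n = x.size();
  int nt = n - m + 1;
  if (nt <= 0) return NA_REAL;
  double acc = 0.0;
  for (int i = 0; i < nt; ++i) {
    int cnt = 0;
    for (int j = 0; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) break;
      }
      if (d <= r) ++cnt;
    }
    acc += std::log((double)cnt / (double)nt);
  }
  return acc / (double)nt;
}

// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  double p1 = phi_apen(x, m, r);
  double p2 = phi_apen(x, m + 1, r);
  if (ISNAN(p1) || ISNAN(p2)) return NA_REAL;
  return p1 - p2;
}

// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;  // comparable templates for both lengths m and m+1
  if (nt <= 1) return NA_REAL;
  long long B = 0, A = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) break;
      }
      if (d <= r) {
        ++B;
        if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
      }
    }
  }
  if (B == 0 || A == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}
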