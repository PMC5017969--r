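#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Direct-form II transposed biquad, single section, explicit initial state.
// [[Rcpp::export(name = ".biquad_cpp")]]
NumericVector biquad_cpp(NumericVector x, NumericVector s, NumericVector zi) {
  const double b0 = s[0], b1 = s[1], b2 = s[2], a1 = s[4], a2 = s[5];
  const int n = x.size();
  NumericVector y(n);
  double z1 = zi[0], z2 = zi[1];
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b0 * xi + z1;
    z1 = b1 * xi - a1 * yi + z2;
    z2 = b2 * xi - a2 * yi;
    y[i] = yi;
  }
  return y;
}

// phi(m) helper used by approximate entropy: mean over i of
// log(C_i^m(r)), with self-matches included (Pincus' definition).
static double apen_phi(const NumericVector& x, int m, double r) {
  const int n = x.size();
  const int nm = n - m + 1;
  double acc = 0.0;
  for (int i = 0; i < nm; ++i) {
    int cnt = 0;
    for (int j = 0; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        const double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
      }
      if (d <= r) ++cnt;
    }
    acc += std::log(static_cast<double>(cnt) / nm);
  }
  return acc / nm;
}

// Approximate entropy ApEn(m, r): phi_m - phi_{m+1}.
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  if (x.size() < m + 2) return 0.0;
  return apen_phi(x, m, r) - apen_phi(x, m + 1, r);
}

// Sample entropy SampEn(m, r): -log(A/B), self-matches excluded.
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  if (n < m + 2) return 0.0;
  const int nm = n - m;  // templates of length m and m+1 both indexable
  long long A = 0, B = 0;
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        const double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
      }
      if (d <= r) {
        ++B;
        const double a = std::fabs(x[i + m] - x[j + m]);
        if (std::max(d, a) <= r) ++A;
      }
    }
  }
  if (B == 0 || A == 0) return 0.0;  // guard: no matches -> undefined, report 0
  return -std::log(static_cast<double>(A) / static_cast<double>(B));
}

// Lempel-Ziv 1976 parsing complexity of a 0/1 sequence.
// [[Rcpp::export(name = ".lz76_cpp")]]
int lz76_cpp(IntegerVector s) {
  const int n = s.size();
  if (n == 0) return 0;
  int c = 1, i = 0, k = 1, kmax = 1, l = 1;
  while (true) {
    if (l + k - 1 >= n) { ++c; break; }
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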