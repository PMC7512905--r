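#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Pairwise template counting for the regularity statistics. All measures
// embed x into delay vectors (lag t) and compare templates under the
// Chebyshev (max-abs) distance. Template indices run over 1..N - m*t at
// BOTH dimensions m and m+1, so the conditional counts are nested and
// ApEn is exactly non-negative.
//
// ApEn/SampEn counting sorts templates by their first component and only
// examines pairs within the tolerance window on that component (a
// necessary condition for a Chebyshev match), which prunes the O(N^2)
// loop without changing any count; correctness is pinned to a naive
// double-loop oracle in the tests.

static inline int n_templates(int n, int m, int t) {
  return n - m * t;
}

static std::vector<int> sorted_order(const NumericVector& x, int nt) {
  std::vector<int> ord(nt);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&x](int a, int b) { return x[a] < x[b]; });
  return ord;
}

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, int t, double r) {
  const int n = x.size();
  const int nt = n_templates(n, m, t);
  if (nt < 1) stop("series too short for the requested embedding");
  // self-match included: every template matches itself at both dimensions
  std::vector<double> cm(nt, 1.0), cm1(nt, 1.0);
  std::vector<int> ord = sorted_order(x, nt);
  for (int a = 0; a < nt; ++a) {
    const int i = ord[a];
    for (int b = a + 1; b < nt && x[ord[b]] - x[i] <= r; ++b) {
      const int j = ord[b];
      bool ok = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(x[i + k * t] - x[j + k * t]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      cm[i] += 1.0; cm[j] += 1.0;
      if (std::fabs(x[i + m * t] - x[j + m * t]) <= r) {
        cm1[i] += 1.0; cm1[j] += 1.0;
      }
    }
  }
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nt; ++i) {
    phi_m += std::log(cm[i] / nt);
    phi_m1 += std::log(cm1[i] / nt);
  }
  return (phi_m - phi_m1) / nt;
}

// Returns the template-pair counts (B at dimension m, A at m + 1),
// self-matches excluded; the wrapper forms -log(A/B).
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, int t, double r) {
  const int n = x.size();
  const int nt = n_templates(n, m, t);
  if (nt < 2) stop("series too short for the requested embedding");
  double A = 0.0, B = 0.0;
  std::vector<int> ord = sorted_order(x, nt);
  for (int a = 0; a < nt; ++a) {
    const int i = ord[a];
    for (int b = a + 1; b < nt && x[ord[b]] - x[i] <= r; ++b) {
      const int j = ord[b];
      bool ok = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(x[i + k * t] - x[j + k * t]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::fabs(x[i + m * t] - x[j + m * t]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}

// Mean exponential similarity of baseline-removed templates at one
// embedding dimension (Chen-style fuzzy entropy building block). The
// membership never truncates to zero, so all pairs are visited.
static double fuzzy_phi(const NumericVector& x, int m, int t, double r,
                        double npow, int nt) {
  const int n_comp = m;
  std::vector<double> tmpl((size_t)nt * n_comp);
  for (int i = 0; i < nt; ++i) {
    double mu = 0.0;
    for (int k = 0; k < n_comp; ++k) mu += x[i + k * t];
    mu /= n_comp;
    for (int k = 0; k < n_comp; ++k)
      tmpl[(size_t)i * n_comp + k] = x[i + k * t] - mu;
  }
  double total = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    const double* ti = &tmpl[(size_t)i * n_comp];
    for (int j = i + 1; j < nt; ++j) {
      const double* tj = &tmpl[(size_t)j * n_comp];
      double d = 0.0;
      for (int k = 0; k < n_comp; ++k) {
        double diff = std::fabs(ti[k] - tj[k]);
        if (diff > d) d = diff;
      }
      total += std::exp(-std::pow(d / r, npow));
    }
  }
  // mean over ordered pairs (i != j); symmetric, so double the i < j sum
  return 2.0 * total / ((double)nt * (nt - 1));
}

// [[Rcpp::export]]
double fuzzyen_cpp(NumericVector x, int m, int t, double r, double npow) {
  const int n = x.size();
  const int nt = n_templates(n, m, t);
  if (nt < 2) stop("series too short for the requested embedding");
  double phi_m = fuzzy_phi(x, m, t, r, npow, nt);
  double phi_m1 = fuzzy_phi(x, m + 1, t, r, npow, nt);
  return std::log(phi_m) - std::log(phi_m1);
}
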