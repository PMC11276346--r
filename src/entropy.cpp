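#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template distance between x[i..i+m-1] and x[j..j+m-1] (0-based i, j).
static inline double tmpl_dist(const double *x, int i, int j, int m,
                               bool chebyshev) {
  if (chebyshev) {
    double mx = 0.0;
    for (int k = 0; k < m; ++k) {
      double d = std::fabs(x[i + k] - x[j + k]);
      if (d > mx) mx = d;
    }
    return mx;
  }
  double s = 0.0;
  for (int k = 0; k < m; ++k) {
    double d = x[i + k] - x[j + k];
    s += d * d;
  }
  return std::sqrt(s);
}

// Per-origin counts of template pairs with d < r over the N - m + 1
// templates of length m. include_self adds the self-pair to every count.
// [[Rcpp::export]]
IntegerVector template_match_counts_cpp(NumericVector x, int m, double r,
                                        bool include_self, bool chebyshev) {
  const int N = x.size();
  const int n = N - m + 1;
  IntegerVector counts(n);
  const double *px = REAL(x);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (tmpl_dist(px, i, j, m, chebyshev) < r) {
        counts[i]++;
        counts[j]++;
      }
    }
    if (include_self) counts[i]++;
  }
  return counts;
}

// Richman-Moorman pair totals: B counts m-template matches, A counts
// (m+1)-template matches, both over the first N - m template origins so
// the two counts are comparable; self-pairs excluded.
// [[Rcpp::export]]
NumericVector sampen_pair_counts_cpp(NumericVector x, int m, double r,
                                     bool chebyshev) {
  const int N = x.size();
  const int n = N - m;
  double A = 0.0, B = 0.0;
  const double *px = REAL(x);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      // both metrics are monotone under template extension, so an
      // (m+1)-match implies an m-match and the extension check can nest
      if (tmpl_dist(px, i, j, m, chebyshev) < r) {
        B += 1.0;
        if (tmpl_dist(px, i, j, m + 1, chebyshev) < r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Mean fuzzy membership phi for templates of length m over the first
// N - m origins, baseline (template mean) removed, membership
// exp(-(d/r)^p); returns c(phi_m, phi_m_plus_1).
// [[Rcpp::export]]
NumericVector fuzzy_phi_cpp(NumericVector x, int m, double r, double p,
                            bool chebyshev) {
  const int N = x.size();
  const int n = N - m;
  NumericVector out(2);
  for (int dim = 0; dim < 2; ++dim) {
    const int mm = m + dim;
    // baseline-subtracted templates, n origins
    std::vector<double> tpl((size_t)n * mm);
    for (int i = 0; i < n; ++i) {
      double mu = 0.0;
      for (int k = 0; k < mm; ++k) mu += x[i + k];
      mu /= mm;
      for (int k = 0; k < mm; ++k) tpl[(size_t)i * mm + k] = x[i + k] - mu;
    }
    // D is symmetric, so accumulate i < j once; memberships below 1e-18
    // (squared distance beyond ~41 r^2 for p = 2) are numerically zero
    const double r2 = r * r;
    const bool p_is_2 = (p == 2.0);
    const double cutoff2 = 41.5 * r2;
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
      const double *ti = &tpl[(size_t)i * mm];
      for (int j = i + 1; j < n; ++j) {
        const double *tj = &tpl[(size_t)j * mm];
        double d2;
        if (chebyshev) {
          double mx = 0.0;
          for (int k = 0; k < mm; ++k) {
            double a = std::fabs(ti[k] - tj[k]);
            if (a > mx) mx = a;
          }
          d2 = mx * mx;
        } else {
          double s = 0.0;
          for (int k = 0; k < mm; ++k) {
            double a = ti[k] - tj[k];
            s += a * a;
          }
          d2 = s;
        }
        if (p_is_2) {
          if (d2 < cutoff2) total += std::exp(-d2 / r2);
        } else {
          total += std::exp(-std::pow(std::sqrt(d2) / r, p));
        }
      }
    }
    out[dim] = 2.0 * total / ((double)n * (n - 1));
  }
  return out;
}
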