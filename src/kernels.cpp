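#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Pair-counting kernels for second-order summary statistics on rectangular
// windows.  All functions accumulate, for every distance r[k] of the grid,
//     sum over pairs of  e_ij * k(d_ij; r[k])
// where e_ij is the translation edge-correction weight
//     e_ij = A / ((Wx - |dx|) * (Wy - |dy|))
// (or 1 when `translation` is false) and k is one of
//   mode 0: ring indicator  1{ d in (r - hw, r + hw] }         (hw = w/2)
//   mode 1: Epanechnikov    0.75/hw * (1 - ((d - r)/hw)^2)_+
//   mode 2: box kernel      1/(2 hw) * 1{ d in (r - hw, r + hw] }
// Normalisation by intensities and ring area / 2 pi r happens in R.

namespace {

inline double edge_weight(double dx, double dy, double wx, double wy,
                          bool translation) {
  if (!translation) return 1.0;
  return (wx * wy) / ((wx - std::fabs(dx)) * (wy - std::fabs(dy)));
}

// accumulate contributions of one pair at distance d with weight e into acc
inline void add_pair(double d, double e, const NumericVector& r, double hw,
                     int mode, double* acc) {
  const int nr = r.size();
  // candidate grid values: r in [d - hw, d + hw)
  int k = std::lower_bound(r.begin(), r.end(), d - hw) - r.begin();
  for (; k < nr && r[k] < d + hw; ++k) {
    double u = d - r[k];            // in (-hw, hw]
    switch (mode) {
    case 0:
      acc[k] += e;
      break;
    case 1: {
      double z = u / hw;
      double v = 1.0 - z * z;
      if (v > 0) acc[k] += e * 0.75 / hw * v;
      break;
    }
    case 2:
      acc[k] += e * 0.5 / hw;
      break;
    }
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_pair_sums(NumericVector x, NumericVector y,
                            double wx, double wy,
                            NumericVector r, double hw,
                            int mode, bool translation) {
  const int n = x.size(), nr = r.size();
  NumericVector out(nr);
  double* acc = REAL(out);
  const double rmax = r[nr - 1] + hw;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d >= rmax) continue;
      double e = edge_weight(dx, dy, wx, wy, translation);
      add_pair(d, 2.0 * e, r, hw, mode, acc); // ordered pairs: count both
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_cross_sums(NumericVector x1, NumericVector y1,
                             NumericVector x2, NumericVector y2,
                             double wx, double wy,
                             NumericVector r, double hw,
                             int mode, bool translation,
                             IntegerVector id1, IntegerVector id2) {
  const int n1 = x1.size(), n2 = x2.size(), nr = r.size();
  const bool use_id = id1.size() == n1 && id2.size() == n2 && n1 > 0;
  NumericVector out(nr);
  double* acc = REAL(out);
  const double rmax = r[nr - 1] + hw;
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) {
      if (use_id && id1[i] == id2[j]) continue; // same physical point
      double dx = x1[i] - x2[j], dy = y1[i] - y2[j];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d >= rmax) continue;
      double e = edge_weight(dx, dy, wx, wy, translation);
      add_pair(d, e, r, hw, mode, acc);
    }
  }
  return out;
}

// Weighted "ring degree" of each point: deg[j, k] = sum over i != j of
// e_ij * k(d_ij; r[k]).  Column sums equal cpp_pair_sums.  Used by the fast
// random-labelling path: with marks m, the numerator of the
// survival-probability statistic (reference = joined pattern) is m' deg.
// [[Rcpp::export]]
NumericMatrix cpp_ring_degree(NumericVector x, NumericVector y,
                              double wx, double wy,
                              NumericVector r, double hw,
                              int mode, bool translation) {
  const int n = x.size(), nr = r.size();
  NumericMatrix out(n, nr);
  double* o = REAL(out);
  const double rmax = r[nr - 1] + hw;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d >= rmax) continue;
      double e = edge_weight(dx, dy, wx, wy, translation);
      int k = std::lower_bound(r.begin(), r.end(), d - hw) - r.begin();
      for (; k < nr && r[k] < d + hw; ++k) {
        double c;
        switch (mode) {
        case 1: {
          double z = (d - r[k]) / hw;
          double v = 1.0 - z * z;
          c = v > 0 ? e * 0.75 / hw * v : 0.0;
          break;
        }
        case 2:
          c = e * 0.5 / hw;
          break;
        default:
          c = e;
        }
        if (c != 0.0) {
          o[i + (R_xlen_t)k * n] += c;
          o[j + (R_xlen_t)k * n] += c;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_neighbour_counts(NumericVector x, NumericVector y,
                                   double radius) {
  const int n = x.size();
  IntegerVector out(n);
  const double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy <= r2) {
        ++out[i];
        ++out[j];
      }
    }
  }
  return out;
}
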