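// Exact Hartigan dip statistic.
//
// D = inf over unimodal CDFs G of sup |F_n - G|.  A unimodal CDF is convex
// left of its mode and concave right of it, and may carry an atom at the
// mode.  For a tolerance e, a fit exists for a given mode position iff
//  (i)  the greatest convex minorant of the ECDF's upper band stays above
//       the lower band on the left part (and symmetrically on the right),
//  (ii) the two sides can be joined monotonically: the minimal achievable
//       end value of the convex part does not exceed the maximal achievable
//       start value of the concave part.  Both extremes are governed by
//       chord-forcing: a convex function that must climb from an upper band
//       at i1 to a lower band at i2 > i1 carries that slope forward.
// The dip is found by bisection on e over all mode positions (between two
// distinct data values, or at one with an atom).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// prefix tolerances of a convex fit: for each prefix 0..j the minimal e such
// that a convex function fits between the staircase bands; `relaxed` drops
// the upper-staircase gap at the last point (mode-at-value case).
static void prefix_tol(int m, const double* v, const double* L, const double* U,
                       std::vector<double>& pre, std::vector<double>& preR) {
  std::vector<double> gap(m, 0.0);
  std::vector<int> hull(m);
  int hlen = 0;
  for (int j = 0; j < m; ++j) {
    while (hlen >= 2) {
      int a = hull[hlen - 2], b = hull[hlen - 1];
      if ((L[b] - L[a]) * (v[j] - v[b]) >= (L[j] - L[b]) * (v[b] - v[a]))
        --hlen;
      else break;
    }
    int anchor = (hlen >= 1) ? hull[hlen - 1] : j;
    hull[hlen++] = j;
    if (anchor < j) {
      double slope = (L[j] - L[anchor]) / (v[j] - v[anchor]);
      for (int i = anchor; i <= j; ++i)
        gap[i] = U[i] - (L[anchor] + (v[i] - v[anchor]) * slope);
    } else {
      gap[j] = U[j] - L[j];
    }
    double mx = 0.0;
    for (int i = 0; i < j; ++i) if (gap[i] > mx) mx = gap[i];
    preR[j] = mx / 2.0;
    if (gap[j] > mx) mx = gap[j];
    pre[j] = mx / 2.0;
  }
}

struct DipGeom {
  int m;
  std::vector<double> v, L, U;
  std::vector<double> pre, preR, suf, sufR;
  std::vector<double> dUL;    // dUL[i1*m+i2] = U[i2] - L[i1]
  std::vector<double> invdv;  // 1 / (v[i2] - v[i1])
};

static bool feasible(const DipGeom& g, double e) {
  const int m = g.m;
  const double tol = 1e-12;
  const double* v = g.v.data();
  const double* L = g.L.data();
  const double* U = g.U.data();
  std::vector<double> s(m, 0.0), s2(m, 0.0);
  for (int i2 = 1; i2 < m; ++i2) {
    double best = 0.0;
    for (int i1 = 0; i1 < i2; ++i1) {
      double c = (g.dUL[(size_t)i1 * m + i2] - 2.0 * e) * g.invdv[(size_t)i1 * m + i2];
      if (c > best) best = c;
    }
    s[i2] = best;
  }
  for (int k1 = 0; k1 < m - 1; ++k1) {
    double best = 0.0;
    for (int k2 = k1 + 1; k2 < m; ++k2) {
      double c = (g.dUL[(size_t)k1 * m + k2] - 2.0 * e) * g.invdv[(size_t)k1 * m + k2];
      if (c > best) best = c;
    }
    s2[k1] = best;
  }
  // ext[j]: floor forced at v[j] by extending chords from earlier points
  // ext2[k]: ceiling forced at v[k] by chords needed later
  std::vector<double> ext(m, R_NegInf), ext2(m, R_PosInf);
  for (int j = 0; j < m; ++j) {
    double best = R_NegInf;
    for (int i2 = 0; i2 < j; ++i2) {
      double c = U[i2] - e + s[i2] * (v[j] - v[i2]);
      if (c > best) best = c;
    }
    ext[j] = best;
  }
  for (int k = 0; k < m; ++k) {
    double best = R_PosInf;
    for (int k1 = k + 1; k1 < m; ++k1) {
      double c = L[k1] + e - s2[k1] * (v[k1] - v[k]);
      if (c < best) best = c;
    }
    ext2[k] = best;
  }
  // mode strictly between v[j-1] and v[j] (j = 0: mode left of all data)
  for (int j = 0; j <= m; ++j) {
    if (j >= 1 && g.pre[j - 1] > e + tol) continue;
    if (j <= m - 1 && g.suf[j] > e + tol) continue;
    if (j >= 1 && j <= m - 1) {
      double minEnd = std::max(U[j - 1] - e, ext[j - 1]);
      double maxStart = std::min(L[j] + e, ext2[j]);
      if (minEnd > maxStart + tol) continue;
    }
    return true;
  }
  // mode at v[j] with an atom
  for (int j = 0; j < m; ++j) {
    if (g.preR[j] > e + tol) continue;
    if (g.sufR[j] > e + tol) continue;
    double minEnd = std::max(L[j] - e, ext[j]);
    double maxStart = std::min(U[j] + e, ext2[j]);
    if (minEnd > maxStart + tol) continue;
    return true;
  }
  return false;
}

// [[Rcpp::export(name = ".dip_cpp")]]
double dip_cpp(NumericVector values, NumericVector lower, NumericVector upper) {
  const int m = values.size();
  if (m == 1) return 0.0;
  DipGeom g;
  g.m = m;
  g.v.assign(values.begin(), values.end());
  g.L.assign(lower.begin(), lower.end());
  g.U.assign(upper.begin(), upper.end());
  g.pre.resize(m); g.preR.resize(m);
  prefix_tol(m, g.v.data(), g.L.data(), g.U.data(), g.pre, g.preR);
  // concave suffix tolerances by reflection (x -> -x, F -> 1 - F)
  {
    std::vector<double> rv(m), rL(m), rU(m), p(m), pR(m);
    for (int i = 0; i < m; ++i) {
      rv[i] = -g.v[m - 1 - i];
      rL[i] = 1.0 - g.U[m - 1 - i];
      rU[i] = 1.0 - g.L[m - 1 - i];
    }
    prefix_tol(m, rv.data(), rL.data(), rU.data(), p, pR);
    g.suf.resize(m); g.sufR.resize(m);
    for (int i = 0; i < m; ++i) {
      g.suf[i] = p[m - 1 - i];
      g.sufR[i] = pR[m - 1 - i];
    }
  }
  g.dUL.resize((size_t)m * m);
  g.invdv.resize((size_t)m * m);
  for (int i1 = 0; i1 < m; ++i1)
    for (int i2 = i1 + 1; i2 < m; ++i2) {
      g.dUL[(size_t)i1 * m + i2] = g.U[i2] - g.L[i1];
      g.invdv[(size_t)i1 * m + i2] = 1.0 / (g.v[i2] - g.v[i1]);
    }
  double lo = 0.0, hi = 0.26;
  if (feasible(g, lo)) return 0.0;
  for (int it = 0; it < 50; ++it) {
    double mid = 0.5 * (lo + hi);
    if (feasible(g, mid)) hi = mid; else lo = mid;
  }
  return 0.5 * (lo + hi);
}
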