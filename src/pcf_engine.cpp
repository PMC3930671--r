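#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Fraction of the circle of radius d centred at (px,py) lying inside the
// rectangle [x0,x1]x[y0,y1] (closed-form for d small enough that the circle
// never crosses two opposite edges, i.e. d < min(side)).
static inline double circle_frac_inside(double px, double py, double d,
                                        double x0, double x1,
                                        double y0, double y1) {
  const double a1 = px - x0, a2 = x1 - px;
  const double b1 = py - y0, b2 = y1 - py;
  auto half_ang = [d](double a) {
    return (a < d) ? std::acos(std::min(1.0, std::max(-1.0, a / d))) : 0.0;
  };
  const double Aa1 = half_ang(a1), Aa2 = half_ang(a2);
  const double Ab1 = half_ang(b1), Ab2 = half_ang(b2);
  double ext = 2.0 * (Aa1 + Aa2 + Ab1 + Ab2);
  const double hp = M_PI / 2.0;
  ext -= std::max(0.0, Aa1 + Ab1 - hp);
  ext -= std::max(0.0, Aa1 + Ab2 - hp);
  ext -= std::max(0.0, Aa2 + Ab1 - hp);
  ext -= std::max(0.0, Aa2 + Ab2 - hp);
  double frac = 1.0 - ext / (2.0 * M_PI);
  return std::max(frac, 1e-12);
}

// [[Rcpp::export]]
NumericVector cpp_ripley_frac(NumericVector px, NumericVector py,
                              NumericVector d,
                              double x0, double x1, double y0, double y1) {
  const R_xlen_t n = px.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = circle_frac_inside(px[i], py[i], d[i], x0, x1, y0, y1);
  return out;
}

static inline double epa(double t, double delta) {
  const double u = t / delta;
  return (std::fabs(u) <= 1.0) ? 0.75 * (1.0 - u * u) / delta : 0.0;
}

// Kernel-smoothed pair sums for the pair correlation function.
// Returns sum over pairs of
//   [k(d-r) + (reflect) k(d+r)] * wsym * rli * rlj / (2 pi divisor)
// where wsym combines the Ripley weights centred at each end point and
// divisor is the pair distance d (divisor_d) or the argument r.
// The caller divides by |W| (and nothing else) to obtain ghat.
// [[Rcpp::export]]
NumericVector cpp_pcf_engine(NumericVector x1, NumericVector y1,
                             NumericVector rl1,
                             NumericVector x2, NumericVector y2,
                             NumericVector rl2,
                             bool cross,
                             double wx0, double wx1, double wy0, double wy1,
                             NumericVector r, double delta,
                             bool divisor_d, bool reflect) {
  const R_xlen_t n1 = x1.size(), n2 = x2.size(), nr = r.size();
  NumericVector out(nr);
  const double rmax = r[nr - 1];
  const double dmax = rmax + delta;
  const double twopi = 2.0 * M_PI;
  std::vector<double> rv(r.begin(), r.end());

  for (R_xlen_t i = 0; i < n1; ++i) {
    const R_xlen_t jstart = cross ? 0 : (i + 1);
    for (R_xlen_t j = jstart; j < n2; ++j) {
      const double dx = x1[i] - x2[j], dy = y1[i] - y2[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 > dmax * dmax || d2 == 0.0) continue;
      const double d = std::sqrt(d2);
      const double wi = 1.0 / circle_frac_inside(x1[i], y1[i], d,
                                                 wx0, wx1, wy0, wy1);
      const double wj = 1.0 / circle_frac_inside(x2[j], y2[j], d,
                                                 wx0, wx1, wy0, wy1);
      // univariate: unordered pair stands for both ordered pairs (w_i + w_j);
      // cross: one ordered pair with the symmetrised weight (w_i + w_j)/2
      const double wsym = cross ? 0.5 * (wi + wj) : (wi + wj);
      const double base = wsym * rl1[i] * rl2[j] / twopi;
      // main kernel term: r in [d - delta, d + delta]
      R_xlen_t lo = std::lower_bound(rv.begin(), rv.end(), d - delta) - rv.begin();
      for (R_xlen_t k = lo; k < nr && rv[k] <= d + delta; ++k) {
        const double div = divisor_d ? d : rv[k];
        out[k] += base * epa(d - rv[k], delta) / div;
      }
      if (reflect && d < delta) {
        // reflection term: r in [0, delta - d]
        for (R_xlen_t k = 0; k < nr && rv[k] <= delta - d; ++k) {
          const double div = divisor_d ? d : rv[k];
          out[k] += base * epa(d + rv[k], delta) / div;
        }
      }
    }
  }
  return out;
}

// Isotropic-corrected K-function pair sums: for each r, sum over ordered
// pairs of w_ij * 1(d_ij <= r).  Caller normalises.
// [[Rcpp::export]]
NumericVector cpp_kest_engine(NumericVector x, NumericVector y,
                              double wx0, double wx1, double wy0, double wy1,
                              NumericVector r) {
  const R_xlen_t n = x.size(), nr = r.size();
  NumericVector bins(nr);
  const double rmax = r[nr - 1];
  std::vector<double> rv(r.begin(), r.end());
  for (R_xlen_t i = 0; i < n; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 > rmax * rmax || d2 == 0.0) continue;
      const double d = std::sqrt(d2);
      const double wi = 1.0 / circle_frac_inside(x[i], y[i], d, wx0, wx1, wy0, wy1);
      const double wj = 1.0 / circle_frac_inside(x[j], y[j], d, wx0, wx1, wy0, wy1);
      R_xlen_t k = std::lower_bound(rv.begin(), rv.end(), d) - rv.begin();
      if (k < nr) bins[k] += wi + wj;
    }
  }
  // cumulative sum over the grid
  for (R_xlen_t k = 1; k < nr; ++k) bins[k] += bins[k - 1];
  return bins;
}

// Pairwise-distance multiset under the wrap (toroidal) metric, used by the
// toroidal-shift invariance checks.
// [[Rcpp::export]]
NumericVector cpp_torus_dists(NumericVector x, NumericVector y,
                              double wx, double wy) {
  const R_xlen_t n = x.size();
  NumericVector out(n * (n - 1) / 2);
  R_xlen_t m = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    for (R_xlen_t j = i + 1; j < n; ++j) {
      double dx = std::fabs(x[i] - x[j]);
      double dy = std::fabs(y[i] - y[j]);
      dx = std::min(dx, wx - dx);
      dy = std::min(dy, wy - dy);
      out[m++] = std::sqrt(dx * dx + dy * dy);
    }
  return out;
}
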