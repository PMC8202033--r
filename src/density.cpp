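#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Promolecule density over atoms with per-element cutoff radii.  Two
// per-element density representations (all lengths in bohr):
//   kind 0: sum of exponential terms  rho(r) = sum_k coef_k r^pow_k e^{-expo_k r}
//   kind 1: log(rho) tabulated on a uniform log(r) grid, linear interpolation
// [[Rcpp::export]]
NumericVector promolecule_density_cpp(NumericMatrix pts, NumericMatrix pos,
                                      IntegerVector atom_elem,
                                      IntegerVector elem_kind,
                                      IntegerVector term_start,
                                      NumericVector coef, NumericVector pow_,
                                      NumericVector expo,
                                      IntegerVector grid_start,
                                      NumericVector grid_logrho,
                                      NumericVector grid_logr0,
                                      NumericVector grid_dlog,
                                      NumericVector rcut) {
  const int m = pts.nrow(), n = pos.nrow();
  NumericVector out(m);
  for (int a = 0; a < n; ++a) {
    const int e = atom_elem[a];
    const double ax = pos(a, 0), ay = pos(a, 1), az = pos(a, 2);
    const double rc = rcut[e], rc2 = rc * rc;
    if (elem_kind[e] == 0) {
      const int t0 = term_start[e], t1 = term_start[e + 1];
      for (int i = 0; i < m; ++i) {
        const double dx = pts(i, 0) - ax, dy = pts(i, 1) - ay, dz = pts(i, 2) - az;
        const double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 > rc2) continue;
        const double r = std::sqrt(r2);
        double v = 0.0;
        for (int t = t0; t < t1; ++t) {
          double rp = (pow_[t] == 0.0) ? 1.0 : std::pow(r, pow_[t]);
          v += coef[t] * rp * std::exp(-expo[t] * r);
        }
        out[i] += v;
      }
    } else {
      const int g0 = grid_start[e], g1 = grid_start[e + 1];
      const int ng = g1 - g0;
      const double lr0 = grid_logr0[e], dl = grid_dlog[e];
      for (int i = 0; i < m; ++i) {
        const double dx = pts(i, 0) - ax, dy = pts(i, 1) - ay, dz = pts(i, 2) - az;
        const double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 > rc2) continue;
        const double r = std::sqrt(r2);
        double t = (0.5 * std::log(r2) - lr0) / dl;
        double v;
        if (t <= 0) {
          v = std::exp(grid_logrho[g0]);
        } else if (t >= ng - 1) {
          // extrapolate with the tail slope of the last grid segment
          double slope = (grid_logrho[g1 - 1] - grid_logrho[g1 - 2]);
          v = std::exp(grid_logrho[g1 - 1] + slope * (t - (ng - 1)));
        } else {
          int k = (int)t;
          double f = t - k;
          v = std::exp(grid_logrho[g0 + k] * (1 - f) + grid_logrho[g0 + k + 1] * f);
        }
        out[i] += v;
      }
    }
  }
  return out;
}

// brute-force nearest neighbour: for every point, index (1-based) and
// distance of the nearest atom
// [[Rcpp::export]]
List nn_brute_cpp(NumericMatrix pts, NumericMatrix atoms) {
  const int m = pts.nrow(), n = atoms.nrow();
  IntegerVector idx(m);
  NumericVector dist(m);
  for (int i = 0; i < m; ++i) {
    double best = R_PosInf; int bj = 0;
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    for (int j = 0; j < n; ++j) {
      const double dx = atoms(j, 0) - px, dy = atoms(j, 1) - py, dz = atoms(j, 2) - pz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
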