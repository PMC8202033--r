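// Gaussian-integral engine (McMurchie-Davidson scheme).
//
// Works over contracted Cartesian Gaussian shells; all quantities in
// atomic units.  Component order within a shell of angular momentum l:
// (i, j, k) with i descending, then j descending (x, y, z for p;
// xx, xy, xz, yy, yz, zz for d).  Each primitive component carries the
// standard Cartesian normalization; final per-AO renormalization to unit
// self-overlap happens on the R side.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
using namespace Rcpp;

static double dfact(int n) {          // (2n-1)!! with dfact(0) = 1
  double r = 1.0;
  for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
  return r;
}

static double prim_norm(double a, int i, int j, int k) {
  int l = i + j + k;
  return std::pow(2.0 * a / M_PI, 0.75) * std::pow(4.0 * a, 0.5 * l) /
         std::sqrt(dfact(i) * dfact(j) * dfact(k));
}

// Boys function F_m(x) for m = 0..mmax
static void boys(int mmax, double x, std::vector<double> &F) {
  F.assign(mmax + 1, 0.0);
  if (x < 1e-14) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2 * m + 1);
    return;
  }
  if (x > 35.0) {
    F[0] = 0.5 * std::sqrt(M_PI / x);
    double ex = std::exp(-x);
    for (int m = 0; m < mmax; ++m) F[m + 1] = ((2 * m + 1) * F[m] - ex) / (2 * x);
    return;
  }
  // series for F_mmax, then downward recursion
  double s = 0.0, term = 1.0 / (2 * mmax + 1);
  for (int i = 0; i < 200; ++i) {
    s += term;
    term *= 2.0 * x / (2 * mmax + 2 * i + 3);
    if (term < 1e-17 * s) break;
  }
  double ex = std::exp(-x);
  F[mmax] = s * ex;
  for (int m = mmax - 1; m >= 0; --m) F[m] = (2 * x * F[m + 1] + ex) / (2 * m + 1);
}

// Hermite expansion coefficients E_t^{ij} along one dimension.
// e(i, j, t) with 0 <= i <= imax, 0 <= j <= jmax, 0 <= t <= i + j.
struct ECoef {
  int imax, jmax;
  std::vector<double> v;
  double &at(int i, int j, int t) {
    return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t];
  }
  void build(int imax_, int jmax_, double a, double b, double AB, double PA, double PB) {
    imax = imax_; jmax = jmax_;
    v.assign((imax + 1) * (jmax + 1) * (imax + jmax + 1), 0.0);
    double p = a + b, mu = a * b / p, o2p = 0.5 / p;
    at(0, 0, 0) = std::exp(-mu * AB * AB);
    for (int i = 1; i <= imax; ++i)
      for (int t = 0; t <= i; ++t) {
        double val = PA * at(i - 1, 0, t);
        if (t > 0) val += o2p * at(i - 1, 0, t - 1);
        if (t + 1 <= i - 1) val += (t + 1) * at(i - 1, 0, t + 1);
        at(i, 0, t) = val;
      }
    for (int j = 1; j <= jmax; ++j)
      for (int i = 0; i <= imax; ++i)
        for (int t = 0; t <= i + j; ++t) {
          double val = PB * at(i, j - 1, t);
          if (t > 0) val += o2p * at(i, j - 1, t - 1);
          if (t + 1 <= i + j - 1) val += (t + 1) * at(i, j - 1, t + 1);
          at(i, j, t) = val;
        }
  }
};

// Hermite Coulomb integrals R_{tuv} = R^0_{tuv}(p, PC) up to total order L
struct RTable {
  int L;
  std::vector<double> v;  // [n][t][u][v]
  double &at(int n, int t, int u, int w) {
    return v[((n * (L + 1) + t) * (L + 1) + u) * (L + 1) + w];
  }
  void build(int L_, double p, double X, double Y, double Z) {
    L = L_;
    double T = p * (X * X + Y * Y + Z * Z);
    std::vector<double> F;
    boys(L, T, F);
    v.assign((L + 1) * (L + 1) * (L + 1) * (L + 1), 0.0);
    double m2p = 1.0;
    for (int n = 0; n <= L; ++n) { at(n, 0, 0, 0) = m2p * F[n]; m2p *= -2.0 * p; }
    for (int n = L - 1; n >= 0; --n)
      for (int ell = 1; ell <= L - n; ++ell)
        for (int t = ell; t >= 0; --t)
          for (int u = ell - t; u >= 0; --u) {
            int w = ell - t - u;
            double val;
            if (t > 0) {
              val = X * at(n + 1, t - 1, u, w);
              if (t > 1) val += (t - 1) * at(n + 1, t - 2, u, w);
            } else if (u > 0) {
              val = Y * at(n + 1, t, u - 1, w);
              if (u > 1) val += (u - 1) * at(n + 1, t, u - 2, w);
            } else {
              val = Z * at(n + 1, t, u, w - 1);
              if (w > 1) val += (w - 1) * at(n + 1, t, u, w - 2);
            }
            at(n, t, u, w) = val;
          }
  }
};

struct Shells {
  IntegerVector l;
  NumericMatrix center;
  IntegerVector pstart;
  NumericVector expo, coef;
  std::vector<int> ao0;   // first Cartesian AO index per shell
  int nao;
  Shells(List s)
      : l(as<IntegerVector>(s["l"])), center(as<NumericMatrix>(s["center"])),
        pstart(as<IntegerVector>(s["prim_start"])),
        expo(as<NumericVector>(s["expo"])), coef(as<NumericVector>(s["coef"])) {
    nao = 0;
    for (int i = 0; i < l.size(); ++i) {
      ao0.push_back(nao);
      nao += (l[i] + 1) * (l[i] + 2) / 2;
    }
  }
  int nshell() const { return l.size(); }
};

// enumerate Cartesian components of angular momentum l
static void components(int l, std::vector<std::array<int, 3>> &comp) {
  comp.clear();
  for (int i = l; i >= 0; --i)
    for (int j = l - i; j >= 0; --j) comp.push_back({i, j, l - i - j});
}

// one-electron overlap and kinetic matrices
// [[Rcpp::export]]
List one_electron_cpp(List shells) {
  Shells sh(shells);
  int n = sh.nao;
  NumericMatrix S(n, n), T(n, n);
  std::vector<std::array<int, 3>> ca, cb;
  for (int A = 0; A < sh.nshell(); ++A)
    for (int B = 0; B <= A; ++B) {
      int la = sh.l[A], lb = sh.l[B];
      components(la, ca); components(lb, cb);
      double AB[3];
      for (int d = 0; d < 3; ++d) AB[d] = sh.center(A, d) - sh.center(B, d);
      int na = ca.size(), nb = cb.size();
      std::vector<double> sblk(na * nb, 0.0), tblk(na * nb, 0.0);
      for (int pa = sh.pstart[A]; pa < sh.pstart[A + 1]; ++pa)
        for (int pb = sh.pstart[B]; pb < sh.pstart[B + 1]; ++pb) {
          double a = sh.expo[pa], b = sh.expo[pb], p = a + b;
          double P[3], PA[3], PB[3];
          for (int d = 0; d < 3; ++d) {
            P[d] = (a * sh.center(A, d) + b * sh.center(B, d)) / p;
            PA[d] = P[d] - sh.center(A, d);
            PB[d] = P[d] - sh.center(B, d);
          }
          ECoef E[3];
          for (int d = 0; d < 3; ++d) E[d].build(la, lb + 2, a, b, AB[d], PA[d], PB[d]);
          double pref = std::pow(M_PI / p, 1.5);
          for (int ia = 0; ia < na; ++ia)
            for (int ib = 0; ib < nb; ++ib) {
              double cc = sh.coef[pa] * sh.coef[pb] *
                          prim_norm(a, ca[ia][0], ca[ia][1], ca[ia][2]) *
                          prim_norm(b, cb[ib][0], cb[ib][1], cb[ib][2]);
              double sd[3], td[3];
              for (int d = 0; d < 3; ++d) {
                int i = ca[ia][d], j = cb[ib][d];
                double s_ij = E[d].at(i, j, 0);
                double s_ij2 = E[d].at(i, j + 2, 0);
                double s_ijm2 = (j >= 2) ? E[d].at(i, j - 2, 0) : 0.0;
                sd[d] = s_ij;
                td[d] = -2.0 * b * b * s_ij2 + b * (2 * j + 1) * s_ij -
                        0.5 * j * (j - 1) * s_ijm2;
              }
              sblk[ia * nb + ib] += cc * pref * sd[0] * sd[1] * sd[2];
              tblk[ia * nb + ib] += cc * pref *
                (td[0] * sd[1] * sd[2] + sd[0] * td[1] * sd[2] + sd[0] * sd[1] * td[2]);
            }
        }
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib) {
          int I = sh.ao0[A] + ia, J = sh.ao0[B] + ib;
          S(I, J) = S(J, I) = sblk[ia * nb + ib];
          T(I, J) = T(J, I) = tblk[ia * nb + ib];
        }
    }
  return List::create(_["S"] = S, _["T"] = T);
}

// sum_k q_k * (mu | 1/|r - C_k| | nu)  (positive integrals, charge-weighted)
// [[Rcpp::export]]
NumericMatrix charge_attraction_cpp(List shells, NumericVector q, NumericMatrix C) {
  Shells sh(shells);
  int n = sh.nao, nq = q.size();
  NumericMatrix V(n, n);
  std::vector<std::array<int, 3>> ca, cb;
  RTable R;
  for (int A = 0; A < sh.nshell(); ++A)
    for (int B = 0; B <= A; ++B) {
      int la = sh.l[A], lb = sh.l[B], L = la + lb;
      components(la, ca); components(lb, cb);
      int na = ca.size(), nb = cb.size();
      std::vector<double> blk(na * nb, 0.0);
      double AB[3];
      for (int d = 0; d < 3; ++d) AB[d] = sh.center(A, d) - sh.center(B, d);
      for (int pa = sh.pstart[A]; pa < sh.pstart[A + 1]; ++pa)
        for (int pb = sh.pstart[B]; pb < sh.pstart[B + 1]; ++pb) {
          double a = sh.expo[pa], b = sh.expo[pb], p = a + b;
          double P[3], PA[3], PB[3];
          for (int d = 0; d < 3; ++d) {
            P[d] = (a * sh.center(A, d) + b * sh.center(B, d)) / p;
            PA[d] = P[d] - sh.center(A, d);
            PB[d] = P[d] - sh.center(B, d);
          }
          ECoef E[3];
          for (int d = 0; d < 3; ++d) E[d].build(la, lb, a, b, AB[d], PA[d], PB[d]);
          double pref = 2.0 * M_PI / p;
          for (int k = 0; k < nq; ++k) {
            R.build(L, p, P[0] - C(k, 0), P[1] - C(k, 1), P[2] - C(k, 2));
            for (int ia = 0; ia < na; ++ia)
              for (int ib = 0; ib < nb; ++ib) {
                double cc = sh.coef[pa] * sh.coef[pb] *
                            prim_norm(a, ca[ia][0], ca[ia][1], ca[ia][2]) *
                            prim_norm(b, cb[ib][0], cb[ib][1], cb[ib][2]);
                double sum = 0.0;
                for (int t = 0; t <= ca[ia][0] + cb[ib][0]; ++t)
                  for (int u = 0; u <= ca[ia][1] + cb[ib][1]; ++u)
                    for (int w = 0; w <= ca[ia][2] + cb[ib][2]; ++w)
                      sum += E[0].at(ca[ia][0], cb[ib][0], t) *
                             E[1].at(ca[ia][1], cb[ib][1], u) *
                             E[2].at(ca[ia][2], cb[ib][2], w) * R.at(0, t, u, w);
                blk[ia * nb + ib] += q[k] * cc * pref * sum;
              }
          }
        }
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib) {
          int I = sh.ao0[A] + ia, J = sh.ao0[B] + ib;
          V(I, J) = blk[ia * nb + ib];
          V(J, I) = blk[ia * nb + ib];
        }
    }
  return V;
}

// electronic ESP term at each point: sum_{mu nu} D_{mu nu} (mu|1/|r-P||nu)
// [[Rcpp::export]]
NumericVector esp_density_cpp(List shells, NumericMatrix D, NumericMatrix pts) {
  Shells sh(shells);
  int np = pts.nrow();
  NumericVector out(np);
  std::vector<std::array<int, 3>> ca, cb;
  RTable R;
  for (int A = 0; A < sh.nshell(); ++A)
    for (int B = 0; B <= A; ++B) {
      int la = sh.l[A], lb = sh.l[B], L = la + lb;
      components(la, ca); components(lb, cb);
      int na = ca.size(), nb = cb.size();
      double AB[3];
      for (int d = 0; d < 3; ++d) AB[d] = sh.center(A, d) - sh.center(B, d);
      double sym = (A == B) ? 1.0 : 2.0;
      for (int pa = sh.pstart[A]; pa < sh.pstart[A + 1]; ++pa)
        for (int pb = sh.pstart[B]; pb < sh.pstart[B + 1]; ++pb) {
          double a = sh.expo[pa], b = sh.expo[pb], p = a + b;
          double P[3], PA[3], PB[3];
          for (int d = 0; d < 3; ++d) {
            P[d] = (a * sh.center(A, d) + b * sh.center(B, d)) / p;
            PA[d] = P[d] - sh.center(A, d);
            PB[d] = P[d] - sh.center(B, d);
          }
          ECoef E[3];
          for (int d = 0; d < 3; ++d) E[d].build(la, lb, a, b, AB[d], PA[d], PB[d]);
          double pref = 2.0 * M_PI / p;
          for (int k = 0; k < np; ++k) {
            R.build(L, p, P[0] - pts(k, 0), P[1] - pts(k, 1), P[2] - pts(k, 2));
            double acc = 0.0;
            for (int ia = 0; ia < na; ++ia)
              for (int ib = 0; ib < nb; ++ib) {
                double cc = sh.coef[pa] * sh.coef[pb] *
                            prim_norm(a, ca[ia][0], ca[ia][1], ca[ia][2]) *
                            prim_norm(b, cb[ib][0], cb[ib][1], cb[ib][2]);
                double sum = 0.0;
                for (int t = 0; t <= ca[ia][0] + cb[ib][0]; ++t)
                  for (int u = 0; u <= ca[ia][1] + cb[ib][1]; ++u)
                    for (int w = 0; w <= ca[ia][2] + cb[ib][2]; ++w)
                      sum += E[0].at(ca[ia][0], cb[ib][0], t) *
                             E[1].at(ca[ia][1], cb[ib][1], u) *
                             E[2].at(ca[ia][2], cb[ib][2], w) * R.at(0, t, u, w);
                acc += sym * D(sh.ao0[A] + ia, sh.ao0[B] + ib) * cc * sum;
              }
            out[k] += pref * acc;
          }
        }
    }
  return out;
}

// Coulomb (J) and exchange (K) matrices for a density matrix D:
//   J_{ab} = sum_{cd} (ab|cd) D_{cd},  K_{ac} = sum_{bd} (ab|cd) D_{bd}
// Plain quadruple shell loop (intended for small monomer/dimer systems).
// [[Rcpp::export]]
List coulomb_JK_cpp(List shells, NumericMatrix D, bool want_K) {
  Shells sh(shells);
  int n = sh.nao, ns = sh.nshell();
  NumericMatrix J(n, n), K(n, n);
  std::vector<std::array<int, 3>> ca, cb, cc_, cd_;
  RTable R;
  for (int A = 0; A < ns; ++A)
  for (int B = 0; B < ns; ++B)
  for (int Cs = 0; Cs < ns; ++Cs)
  for (int Ds = 0; Ds < ns; ++Ds) {
    int la = sh.l[A], lb = sh.l[B], lc = sh.l[Cs], ld = sh.l[Ds];
    int L = la + lb + lc + ld;
    components(la, ca); components(lb, cb);
    components(lc, cc_); components(ld, cd_);
    int na = ca.size(), nb = cb.size(), nc = cc_.size(), nd = cd_.size();
    std::vector<double> blk(na * nb * nc * nd, 0.0);
    double AB[3], CD[3];
    for (int d = 0; d < 3; ++d) {
      AB[d] = sh.center(A, d) - sh.center(B, d);
      CD[d] = sh.center(Cs, d) - sh.center(Ds, d);
    }
    for (int pa = sh.pstart[A]; pa < sh.pstart[A + 1]; ++pa)
    for (int pb = sh.pstart[B]; pb < sh.pstart[B + 1]; ++pb) {
      double a = sh.expo[pa], b = sh.expo[pb], p = a + b;
      double P[3], PA[3], PB[3];
      for (int d = 0; d < 3; ++d) {
        P[d] = (a * sh.center(A, d) + b * sh.center(B, d)) / p;
        PA[d] = P[d] - sh.center(A, d);
        PB[d] = P[d] - sh.center(B, d);
      }
      ECoef Eab[3];
      for (int d = 0; d < 3; ++d) Eab[d].build(la, lb, a, b, AB[d], PA[d], PB[d]);
      for (int pc = sh.pstart[Cs]; pc < sh.pstart[Cs + 1]; ++pc)
      for (int pd = sh.pstart[Ds]; pd < sh.pstart[Ds + 1]; ++pd) {
        double c = sh.expo[pc], dd = sh.expo[pd], q = c + dd;
        double Q[3], QC[3], QD[3];
        for (int d = 0; d < 3; ++d) {
          Q[d] = (c * sh.center(Cs, d) + dd * sh.center(Ds, d)) / q;
          QC[d] = Q[d] - sh.center(Cs, d);
          QD[d] = Q[d] - sh.center(Ds, d);
        }
        ECoef Ecd[3];
        for (int d = 0; d < 3; ++d) Ecd[d].build(lc, ld, c, dd, CD[d], QC[d], QD[d]);
        double alpha = p * q / (p + q);
        R.build(L, alpha, P[0] - Q[0], P[1] - Q[1], P[2] - Q[2]);
        double pref = 2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(p + q));
        int idx = 0;
        for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib)
        for (int ic = 0; ic < nc; ++ic)
        for (int id = 0; id < nd; ++id, ++idx) {
          double cna = prim_norm(a, ca[ia][0], ca[ia][1], ca[ia][2]);
          double cnb = prim_norm(b, cb[ib][0], cb[ib][1], cb[ib][2]);
          double cnc = prim_norm(c, cc_[ic][0], cc_[ic][1], cc_[ic][2]);
          double cnd = prim_norm(dd, cd_[id][0], cd_[id][1], cd_[id][2]);
          double cfac = sh.coef[pa] * sh.coef[pb] * sh.coef[pc] * sh.coef[pd] *
                        cna * cnb * cnc * cnd;
          double sum = 0.0;
          for (int t = 0; t <= ca[ia][0] + cb[ib][0]; ++t)
          for (int u = 0; u <= ca[ia][1] + cb[ib][1]; ++u)
          for (int w = 0; w <= ca[ia][2] + cb[ib][2]; ++w) {
            double eab = Eab[0].at(ca[ia][0], cb[ib][0], t) *
                         Eab[1].at(ca[ia][1], cb[ib][1], u) *
                         Eab[2].at(ca[ia][2], cb[ib][2], w);
            if (eab == 0.0) continue;
            for (int t2 = 0; t2 <= cc_[ic][0] + cd_[id][0]; ++t2)
            for (int u2 = 0; u2 <= cc_[ic][1] + cd_[id][1]; ++u2)
            for (int w2 = 0; w2 <= cc_[ic][2] + cd_[id][2]; ++w2) {
              double ecd = Ecd[0].at(cc_[ic][0], cd_[id][0], t2) *
                           Ecd[1].at(cc_[ic][1], cd_[id][1], u2) *
                           Ecd[2].at(cc_[ic][2], cd_[id][2], w2);
              if (ecd == 0.0) continue;
              double sgn = ((t2 + u2 + w2) % 2) ? -1.0 : 1.0;
              sum += eab * ecd * sgn * R.at(0, t + t2, u + u2, w + w2);
            }
          }
          blk[idx] += cfac * pref * sum;
        }
      }
    }
    int idx = 0;
    for (int ia = 0; ia < na; ++ia)
    for (int ib = 0; ib < nb; ++ib)
    for (int ic = 0; ic < nc; ++ic)
    for (int id = 0; id < nd; ++id, ++idx) {
      int I = sh.ao0[A] + ia, Jj = sh.ao0[B] + ib;
      int Kk = sh.ao0[Cs] + ic, Ll = sh.ao0[Ds] + id;
      double v = blk[idx];
      J(I, Jj) += v * D(Kk, Ll);
      if (want_K) K(I, Kk) += v * D(Jj, Ll);
    }
  }
  return List::create(_["J"] = J, _["K"] = K);
}

// full packed ERI list (p>=q, pq>=rs canonical order) for small bases;
// intended for one-off atomic SCF table generation
// [[Rcpp::export]]
NumericVector eri_packed_cpp(List shells) {
  Shells sh(shells);
  int n = sh.nao;
  long npair = (long)n * (n + 1) / 2;
  NumericVector out((R_xlen_t)(npair * (npair + 1) / 2));
  std::vector<std::array<int, 3>> ca, cb, cc_, cd_;
  RTable R;
  int ns = sh.nshell();
  for (int A = 0; A < ns; ++A)
  for (int B = 0; B <= A; ++B)
  for (int Cs = 0; Cs <= A; ++Cs)
  for (int Ds = 0; Ds <= (Cs == A ? B : Cs); ++Ds) {
    int la = sh.l[A], lb = sh.l[B], lc = sh.l[Cs], ld = sh.l[Ds];
    int L = la + lb + lc + ld;
    components(la, ca); components(lb, cb);
    components(lc, cc_); components(ld, cd_);
    int na = ca.size(), nb = cb.size(), nc = cc_.size(), nd = cd_.size();
    std::vector<double> blk(na * nb * nc * nd, 0.0);
    double AB[3], CD[3];
    for (int d = 0; d < 3; ++d) {
      AB[d] = sh.center(A, d) - sh.center(B, d);
      CD[d] = sh.center(Cs, d) - sh.center(Ds, d);
    }
    for (int pa = sh.pstart[A]; pa < sh.pstart[A + 1]; ++pa)
    for (int pb = sh.pstart[B]; pb < sh.pstart[B + 1]; ++pb) {
      double a = sh.expo[pa], b = sh.expo[pb], p = a + b;
      double P[3], PA[3], PB[3];
      for (int d = 0; d < 3; ++d) {
        P[d] = (a * sh.center(A, d) + b * sh.center(B, d)) / p;
        PA[d] = P[d] - sh.center(A, d);
        PB[d] = P[d] - sh.center(B, d);
      }
      ECoef Eab[3];
      for (int d = 0; d < 3; ++d) Eab[d].build(la, lb, a, b, AB[d], PA[d], PB[d]);
      for (int pc = sh.pstart[Cs]; pc < sh.pstart[Cs + 1]; ++pc)
      for (int pd = sh.pstart[Ds]; pd < sh.pstart[Ds + 1]; ++pd) {
        double c = sh.expo[pc], dd = sh.expo[pd], q = c + dd;
        double Q[3], QC[3], QD[3];
        for (int d = 0; d < 3; ++d) {
          Q[d] = (c * sh.center(Cs, d) + dd * sh.center(Ds, d)) / q;
          QC[d] = Q[d] - sh.center(Cs, d);
          QD[d] = Q[d] - sh.center(Ds, d);
        }
        ECoef Ecd[3];
        for (int d = 0; d < 3; ++d) Ecd[d].build(lc, ld, c, dd, CD[d], QC[d], QD[d]);
        double alpha = p * q / (p + q);
        R.build(L, alpha, P[0] - Q[0], P[1] - Q[1], P[2] - Q[2]);
        double pref = 2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(p + q));
        int idx = 0;
        for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib)
        for (int ic = 0; ic < nc; ++ic)
        for (int id = 0; id < nd; ++id, ++idx) {
          double cfac = sh.coef[pa] * sh.coef[pb] * sh.coef[pc] * sh.coef[pd] *
            prim_norm(a, ca[ia][0], ca[ia][1], ca[ia][2]) *
            prim_norm(b, cb[ib][0], cb[ib][1], cb[ib][2]) *
            prim_norm(c, cc_[ic][0], cc_[ic][1], cc_[ic][2]) *
            prim_norm(dd, cd_[id][0], cd_[id][1], cd_[id][2]);
          double sum = 0.0;
          for (int t = 0; t <= ca[ia][0] + cb[ib][0]; ++t)
          for (int u = 0; u <= ca[ia][1] + cb[ib][1]; ++u)
          for (int w = 0; w <= ca[ia][2] + cb[ib][2]; ++w) {
            double eab = Eab[0].at(ca[ia][0], cb[ib][0], t) *
                         Eab[1].at(ca[ia][1], cb[ib][1], u) *
                         Eab[2].at(ca[ia][2], cb[ib][2], w);
            if (eab == 0.0) continue;
            for (int t2 = 0; t2 <= cc_[ic][0] + cd_[id][0]; ++t2)
            for (int u2 = 0; u2 <= cc_[ic][1] + cd_[id][1]; ++u2)
            for (int w2 = 0; w2 <= cc_[ic][2] + cd_[id][2]; ++w2) {
              double ecd = Ecd[0].at(cc_[ic][0], cd_[id][0], t2) *
                           Ecd[1].at(cc_[ic][1], cd_[id][1], u2) *
                           Ecd[2].at(cc_[ic][2], cd_[id][2], w2);
              if (ecd == 0.0) continue;
              double sgn = ((t2 + u2 + w2) % 2) ? -1.0 : 1.0;
              sum += eab * ecd * sgn * R.at(0, t + t2, u + u2, w + w2);
            }
          }
          blk[idx] += cfac * pref * sum;
        }
      }
    }
    auto pidx = [](long i, long j) { return (i >= j) ? i * (i + 1) / 2 + j
                                                     : j * (j + 1) / 2 + i; };
    int idx = 0;
    for (int ia = 0; ia < na; ++ia)
    for (int ib = 0; ib < nb; ++ib)
    for (int ic = 0; ic < nc; ++ic)
    for (int id = 0; id < nd; ++id, ++idx) {
      long I = sh.ao0[A] + ia, Jj = sh.ao0[B] + ib;
      long Kk = sh.ao0[Cs] + ic, Ll = sh.ao0[Ds] + id;
      long pq = pidx(I, Jj), rs = pidx(Kk, Ll);
      out[(R_xlen_t)pidx(pq, rs)] = blk[idx];
    }
  }
  return out;
}

// J and K matrices from a packed ERI list
// [[Rcpp::export]]
List jk_packed_cpp(NumericVector eri, NumericMatrix D) {
  int n = D.nrow();
  NumericMatrix J(n, n), K(n, n);
  auto pidx = [](long i, long j) { return (i >= j) ? i * (i + 1) / 2 + j
                                                   : j * (j + 1) / 2 + i; };
  for (int p = 0; p < n; ++p)
  for (int q = 0; q <= p; ++q) {
    long pq = pidx(p, q);
    for (int r = 0; r < n; ++r)
    for (int s = 0; s <= r; ++s) {
      long rs = pidx(r, s);
      if (rs > pq) continue;
      double v = eri[(R_xlen_t)pidx(pq, rs)];
      if (v == 0.0) continue;
      double dD_rs = (r == s) ? D(r, s) : D(r, s) + D(s, r);
      double dD_pq = (p == q) ? D(p, q) : D(p, q) + D(q, p);
      J(p, q) += v * dD_rs;
      if (pq != rs) J(r, s) += v * dD_pq;
      // exchange: K_{pr} += (pq|rs) D_{qs} over all 8 permutations
      // handle by explicit expansion of the canonical quartet
      double vv = v;
      auto addK = [&](int a, int b, int c, int d) {
        K(a, c) += vv * D(b, d);
      };
      // permutations of (p,q,r,s): (pq|rs),(qp|rs),(pq|sr),(qp|sr),
      // (rs|pq),(sr|pq),(rs|qp),(sr|qp) -- deduplicated
      bool pq_same = (p == q), rs_same = (r == s), pqrs_same = (pq == rs);
      addK(p, q, r, s);
      if (!pq_same) addK(q, p, r, s);
      if (!rs_same) addK(p, q, s, r);
      if (!pq_same && !rs_same) addK(q, p, s, r);
      if (!pqrs_same) {
        addK(r, s, p, q);
        if (!rs_same) addK(s, r, p, q);
        if (!pq_same) addK(r, s, q, p);
        if (!rs_same && !pq_same) addK(s, r, q, p);
      }
    }
  }
  for (int p = 0; p < n; ++p)
  for (int q = 0; q < p; ++q) J(q, p) = J(p, q);
  return List::create(_["J"] = J, _["K"] = K);
}
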