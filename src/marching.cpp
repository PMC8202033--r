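#include <Rcpp.h>
#include <map>
#include <cmath>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra on a regular grid.
//
// Each grid cube is split into six tetrahedra sharing the 0-6 body
// diagonal; the decomposition is translation invariant, so shared cube
// faces are split along matching diagonals and the resulting mesh is
// watertight.  Vertices are created once per crossing grid edge (global
// corner index pair) and linearly interpolated; the endpoints of each
// crossing edge are returned so callers can refine vertices by bisection
// against the exact field.
//
// Grid layout: values[ix + nx*(iy + ny*iz)], corner (ix,iy,iz) at
// origin + ix*ax + iy*ay + iz*az.

static const int CUBE[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
// six tetrahedra around the 0-6 diagonal
static const int TETS[6][4] = {
  {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};

struct EdgeKey {
  long a, b;
  bool operator<(const EdgeKey &o) const {
    return a < o.a || (a == o.a && b < o.b);
  }
};

// [[Rcpp::export]]
List marching_tetrahedra_cpp(NumericVector values, IntegerVector dims,
                             NumericVector origin, NumericMatrix axes,
                             double isovalue, bool inside_is_high) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::map<EdgeKey, int> edge_vertex;
  std::vector<double> vx, vy, vz, vt;
  std::vector<long> ea, eb;
  std::vector<int> f0, f1, f2;

  auto gidx = [&](int ix, int iy, int iz) -> long {
    return (long)ix + (long)nx * ((long)iy + (long)ny * iz);
  };
  auto corner_pos = [&](long g, double *p) {
    int ix = (int)(g % nx);
    int iy = (int)((g / nx) % ny);
    int iz = (int)(g / ((long)nx * ny));
    for (int d = 0; d < 3; ++d)
      p[d] = origin[d] + ix * axes(0, d) + iy * axes(1, d) + iz * axes(2, d);
  };
  auto edge_vert = [&](long ga, long gb) -> int {
    if (ga > gb) std::swap(ga, gb);
    EdgeKey k{ga, gb};
    auto it = edge_vertex.find(k);
    if (it != edge_vertex.end()) return it->second;
    double fa = values[ga], fb = values[gb];
    double t = (isovalue - fa) / (fb - fa);
    if (t < 0) t = 0; if (t > 1) t = 1;
    double pa[3], pb[3];
    corner_pos(ga, pa); corner_pos(gb, pb);
    int id = (int)vx.size();
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    vt.push_back(t);
    ea.push_back(ga); eb.push_back(gb);
    edge_vertex[k] = id;
    return id;
  };
  // emit triangle oriented so the normal points away from the high-field
  // side (flip afterwards for the opposite convention)
  auto emit = [&](int a, int b, int c, const double *inside_pt) {
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz, nzv = ux * wy - uy * wx;
    double cxv = (vx[a] + vx[b] + vx[c]) / 3.0 - inside_pt[0];
    double cyv = (vy[a] + vy[b] + vy[c]) / 3.0 - inside_pt[1];
    double czv = (vz[a] + vz[b] + vz[c]) / 3.0 - inside_pt[2];
    bool ok = (nxv * cxv + nyv * cyv + nzv * czv) >= 0;  // normal away from inside
    if (!inside_is_high) ok = !ok;
    if (ok) { f0.push_back(a); f1.push_back(b); f2.push_back(c); }
    else    { f0.push_back(a); f1.push_back(c); f2.push_back(b); }
  };

  for (int iz = 0; iz < nz - 1; ++iz)
  for (int iy = 0; iy < ny - 1; ++iy)
  for (int ix = 0; ix < nx - 1; ++ix) {
    long g[8]; double fv[8];
    bool any_hi = false, any_lo = false;
    for (int c = 0; c < 8; ++c) {
      g[c] = gidx(ix + CUBE[c][0], iy + CUBE[c][1], iz + CUBE[c][2]);
      fv[c] = values[g[c]];
      if (fv[c] > isovalue) any_hi = true; else any_lo = true;
    }
    if (!any_hi || !any_lo) continue;
    for (int t = 0; t < 6; ++t) {
      const int *T = TETS[t];
      int hi[4], lo[4]; int nhi = 0, nlo = 0;
      for (int c = 0; c < 4; ++c) {
        if (fv[T[c]] > isovalue) hi[nhi++] = T[c]; else lo[nlo++] = T[c];
      }
      if (nhi == 0 || nhi == 4) continue;
      // mean position of high-field corners = "inside" reference
      double ip[3] = {0, 0, 0}, pc[3];
      for (int c = 0; c < nhi; ++c) {
        corner_pos(g[hi[c]], pc);
        ip[0] += pc[0] / nhi; ip[1] += pc[1] / nhi; ip[2] += pc[2] / nhi;
      }
      if (nhi == 1) {
        int a = edge_vert(g[hi[0]], g[lo[0]]);
        int b = edge_vert(g[hi[0]], g[lo[1]]);
        int c = edge_vert(g[hi[0]], g[lo[2]]);
        emit(a, b, c, ip);
      } else if (nhi == 3) {
        int a = edge_vert(g[lo[0]], g[hi[0]]);
        int b = edge_vert(g[lo[0]], g[hi[1]]);
        int c = edge_vert(g[lo[0]], g[hi[2]]);
        emit(a, b, c, ip);
      } else {  // 2 high, 2 low -> quad
        int a = edge_vert(g[hi[0]], g[lo[0]]);
        int b = edge_vert(g[hi[0]], g[lo[1]]);
        int c = edge_vert(g[hi[1]], g[lo[1]]);
        int d = edge_vert(g[hi[1]], g[lo[0]]);
        emit(a, b, c, ip);
        emit(a, c, d, ip);
      }
    }
  }

  const int nv = (int)vx.size(), nf = (int)f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  NumericVector T(nv);
  NumericVector EA(nv), EB(nv);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i];
    T[i] = vt[i]; EA[i] = (double)(ea[i] + 1); EB[i] = (double)(eb[i] + 1);
  }
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = f0[i] + 1; F(i, 1) = f1[i] + 1; F(i, 2) = f2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F, _["t"] = T,
                      _["edge_a"] = EA, _["edge_b"] = EB);
}

// per-vertex area (one third of incident triangle areas), area-weighted
// vertex normals, total area and signed volume (divergence theorem)
// [[Rcpp::export]]
List mesh_vertex_data_cpp(NumericMatrix V, IntegerMatrix F) {
  const int nv = V.nrow(), nf = F.nrow();
  NumericVector varea(nv);
  NumericMatrix vnorm(nv, 3);
  double area = 0.0, vol6 = 0.0;
  for (int f = 0; f < nf; ++f) {
    const int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    double ux = V(b,0)-V(a,0), uy = V(b,1)-V(a,1), uz = V(b,2)-V(a,2);
    double wx = V(c,0)-V(a,0), wy = V(c,1)-V(a,1), wz = V(c,2)-V(a,2);
    double nx = uy*wz - uz*wy, ny = uz*wx - ux*wz, nz = ux*wy - uy*wx;
    double a2 = std::sqrt(nx*nx + ny*ny + nz*nz);
    area += 0.5 * a2;
    vol6 += V(a,0)*(V(b,1)*V(c,2)-V(b,2)*V(c,1))
          - V(a,1)*(V(b,0)*V(c,2)-V(b,2)*V(c,0))
          + V(a,2)*(V(b,0)*V(c,1)-V(b,1)*V(c,0));
    double third = a2 / 6.0;  // (0.5*a2)/3
    varea[a] += third; varea[b] += third; varea[c] += third;
    for (int k = 0; k < 3; ++k) {
      double nk = (k==0) ? nx : (k==1) ? ny : nz;
      vnorm(a,k) += nk; vnorm(b,k) += nk; vnorm(c,k) += nk;
    }
  }
  for (int i = 0; i < nv; ++i) {
    double n = std::sqrt(vnorm(i,0)*vnorm(i,0) + vnorm(i,1)*vnorm(i,1) +
                         vnorm(i,2)*vnorm(i,2));
    if (n > 0) for (int k = 0; k < 3; ++k) vnorm(i,k) /= n;
  }
  return List::create(_["vertex_area"] = varea, _["normals"] = vnorm,
                      _["area"] = area, _["volume"] = vol6 / 6.0);
}
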