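#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Moller-Trumbore ray/triangle intersection.  Returns t >= 0 or -1 on miss.
static inline double ray_tri(const double* o, const double* d,
                             const double* v0, const double* v1,
                             const double* v2) {
  const double eps = 1e-12;
  double e1[3] = {v1[0] - v0[0], v1[1] - v0[1], v1[2] - v0[2]};
  double e2[3] = {v2[0] - v0[0], v2[1] - v0[1], v2[2] - v0[2]};
  double p[3] = {d[1] * e2[2] - d[2] * e2[1],
                 d[2] * e2[0] - d[0] * e2[2],
                 d[0] * e2[1] - d[1] * e2[0]};
  double det = e1[0] * p[0] + e1[1] * p[1] + e1[2] * p[2];
  if (std::fabs(det) < eps) return -1.0;
  double inv = 1.0 / det;
  double tv[3] = {o[0] - v0[0], o[1] - v0[1], o[2] - v0[2]};
  double u = (tv[0] * p[0] + tv[1] * p[1] + tv[2] * p[2]) * inv;
  if (u < -1e-12 || u > 1.0 + 1e-12) return -1.0;
  double q[3] = {tv[1] * e1[2] - tv[2] * e1[1],
                 tv[2] * e1[0] - tv[0] * e1[2],
                 tv[0] * e1[1] - tv[1] * e1[0]};
  double v = (d[0] * q[0] + d[1] * q[1] + d[2] * q[2]) * inv;
  if (v < -1e-12 || u + v > 1.0 + 1e-12) return -1.0;
  double t = (e2[0] * q[0] + e2[1] * q[1] + e2[2] * q[2]) * inv;
  return t >= 0 ? t : -1.0;
}

// First-hit distance along each ray (Inf on miss) and 1-based index of the
// triangle hit (0 on miss).  V: nv x 3 vertices, F: nf x 3 1-based faces,
// O/D: nray x 3 origins and directions.
// [[Rcpp::export(name = ".raycast_mesh")]]
List raycast_mesh(NumericMatrix V, IntegerMatrix F,
                  NumericMatrix O, NumericMatrix D) {
  int nf = F.nrow(), nr = O.nrow();
  std::vector<double> vx(V.nrow() * 3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int k = 0; k < 3; ++k) vx[3 * i + k] = V(i, k);
  NumericVector out(nr, R_PosInf);
  IntegerVector face(nr, 0);
  for (int r = 0; r < nr; ++r) {
    double o[3] = {O(r, 0), O(r, 1), O(r, 2)};
    double d[3] = {D(r, 0), D(r, 1), D(r, 2)};
    double best = R_PosInf;
    int bestf = 0;
    for (int f = 0; f < nf; ++f) {
      double t = ray_tri(o, d, &vx[3 * (F(f, 0) - 1)],
                         &vx[3 * (F(f, 1) - 1)], &vx[3 * (F(f, 2) - 1)]);
      if (t >= 0 && t < best) { best = t; bestf = f + 1; }
    }
    out[r] = best;
    face[r] = bestf;
  }
  return List::create(_["t"] = out, _["face"] = face);
}

// Watertight-mesh voxelization by parity counting along +x columns.
// Returns a logical vector (column-major, dims nx*ny*nz): voxel centre
// inside the mesh.  origin = world position of voxel centre (1,1,1).
// [[Rcpp::export(name = ".voxelize_mesh")]]
LogicalVector voxelize_mesh(NumericMatrix V, IntegerMatrix F,
                            NumericVector origin, NumericVector spacing,
                            IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nf = F.nrow();
  LogicalVector out(nx * ny * nz, false);
  double x0 = origin[0] - spacing[0];  // ray start strictly before first centre
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + k * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + j * spacing[1];
      double o[3] = {x0, y, z};
      double d[3] = {1.0, 0.0, 0.0};
      std::vector<double> ts;
      for (int f = 0; f < nf; ++f) {
        double v0[3] = {V(F(f, 0) - 1, 0), V(F(f, 0) - 1, 1), V(F(f, 0) - 1, 2)};
        double v1[3] = {V(F(f, 1) - 1, 0), V(F(f, 1) - 1, 1), V(F(f, 1) - 1, 2)};
        double v2[3] = {V(F(f, 2) - 1, 0), V(F(f, 2) - 1, 1), V(F(f, 2) - 1, 2)};
        double t = ray_tri(o, d, v0, v1, v2);
        if (t >= 0) ts.push_back(t);
      }
      if (ts.empty()) continue;
      std::sort(ts.begin(), ts.end());
      // de-duplicate near-identical hits (shared edges)
      std::vector<double> tu;
      for (double t : ts)
        if (tu.empty() || t - tu.back() > 1e-9) tu.push_back(t);
      // parity fill: centres between (t0,t1), (t2,t3), ...
      for (size_t p = 0; p + 1 < tu.size(); p += 2) {
        double xa = x0 + tu[p], xb = x0 + tu[p + 1];
        int ia = (int)std::ceil((xa - origin[0]) / spacing[0] - 1e-12);
        int ib = (int)std::floor((xb - origin[0]) / spacing[0] + 1e-12);
        if (ia < 0) ia = 0;
        if (ib > nx - 1) ib = nx - 1;
        for (int i = ia; i <= ib; ++i)
          out[i + nx * (j + (size_t)ny * k)] = true;
      }
    }
  }
  return out;
}
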