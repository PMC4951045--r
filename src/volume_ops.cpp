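#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Binary morphology and labelling on column-major 3-D masks.

static void ball_offsets(double r, std::vector<std::array<int, 3>>& rel) {
  int ri = (int)std::floor(r);
  rel.clear();
  for (int dz = -ri; dz <= ri; ++dz)
    for (int dy = -ri; dy <= ri; ++dy)
      for (int dx = -ri; dx <= ri; ++dx)
        if (dx * dx + dy * dy + dz * dz <= r * r + 1e-9)
          rel.push_back({dx, dy, dz});
}

static LogicalVector morph(LogicalVector mask, IntegerVector dims, double r,
                           bool dilate) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<std::array<int, 3>> rel;
  ball_offsets(r, rel);
  LogicalVector out(mask.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool acc = !dilate;
        for (auto& o : rel) {
          int x = i + o[0], y = j + o[1], z = k + o[2];
          bool v;
          if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz)
            v = false;  // outside treated as background
          else
            v = mask[x + nx * (y + (size_t)ny * z)];
          if (dilate) { if (v) { acc = true; break; } }
          else        { if (!v) { acc = false; break; } }
        }
        out[i + nx * (j + (size_t)ny * k)] = acc;
      }
  return out;
}

// [[Rcpp::export(name = ".binary_close")]]
LogicalVector binary_close(LogicalVector mask, IntegerVector dims, double r) {
  return morph(morph(mask, dims, r, true), dims, r, false);
}

// Largest 26-connected foreground component.
// [[Rcpp::export(name = ".largest_component26")]]
LogicalVector largest_component26(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<int> label(n, 0);
  int nlab = 0, best = 0;
  size_t bestsize = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || label[s]) continue;
    ++nlab;
    size_t size = 0;
    stack.clear();
    stack.push_back(s);
    label[s] = nlab;
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      ++size;
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int x = i + dx, y = j + dy, z = k + dz;
            if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz)
              continue;
            size_t q = x + nx * (y + (size_t)ny * z);
            if (mask[q] && !label[q]) { label[q] = nlab; stack.push_back(q); }
          }
    }
    if (size > bestsize) { bestsize = size; best = nlab; }
  }
  LogicalVector out(n, false);
  for (size_t s = 0; s < n; ++s) out[s] = (label[s] == best);
  return out;
}

// Fill background holes slice-by-slice (z slices, 4-connectivity in-plane).
// [[Rcpp::export(name = ".fill_holes_slices")]]
LogicalVector fill_holes_slices(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(clone(mask));
  std::vector<char> reach((size_t)nx * ny);
  std::vector<int> stack;
  for (int k = 0; k < nz; ++k) {
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    size_t off = (size_t)nx * ny * k;
    auto push = [&](int i, int j) {
      size_t q = i + (size_t)nx * j;
      if (!reach[q] && !mask[off + q]) { reach[q] = 1; stack.push_back((int)q); }
    };
    for (int i = 0; i < nx; ++i) { push(i, 0); push(i, ny - 1); }
    for (int j = 0; j < ny; ++j) { push(0, j); push(nx - 1, j); }
    while (!stack.empty()) {
      int q = stack.back();
      stack.pop_back();
      int i = q % nx, j = q / nx;
      if (i > 0) push(i - 1, j);
      if (i < nx - 1) push(i + 1, j);
      if (j > 0) push(i, j - 1);
      if (j < ny - 1) push(i, j + 1);
    }
    for (size_t q = 0; q < (size_t)nx * ny; ++q)
      if (!mask[off + q] && !reach[q]) out[off + q] = true;
  }
  return out;
}

// Vertices of the 0.5-level isosurface of a binary mask: midpoints of all
// grid edges joining a foreground and a background voxel centre (the
// marching-cubes vertex set at iso 0.5).  Returns m x 3 voxel coordinates
// (0-based, continuous).
// [[Rcpp::export(name = ".isosurface_points")]]
NumericMatrix isosurface_points(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> pts;
  auto at = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return mask[i + nx * (j + (size_t)ny * k)];
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool a = at(i, j, k);
        // +x, +y, +z edges (and boundary edges to implicit background)
        const int d[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
        for (int e = 0; e < 3; ++e) {
          bool b = at(i + d[e][0], j + d[e][1], k + d[e][2]);
          if (a != b) {
            pts.push_back(i + 0.5 * d[e][0]);
            pts.push_back(j + 0.5 * d[e][1]);
            pts.push_back(k + 0.5 * d[e][2]);
          }
        }
        // -x/-y/-z boundary edges of the grid
        if (a) {
          for (int e = 0; e < 3; ++e) {
            int x = i - d[e][0], y = j - d[e][1], z = k - d[e][2];
            if (x < 0 || y < 0 || z < 0) {
              pts.push_back(i - 0.5 * d[e][0]);
              pts.push_back(j - 0.5 * d[e][1]);
              pts.push_back(k - 0.5 * d[e][2]);
            }
          }
        }
      }
  int m = pts.size() / 3;
  NumericMatrix out(m, 3);
  for (int r = 0; r < m; ++r)
    for (int c = 0; c < 3; ++c) out(r, c) = pts[3 * r + c];
  return out;
}

// Separable Gaussian blur of a 3-D scalar field (reflected boundaries).
// [[Rcpp::export(name = ".gaussian_blur3")]]
NumericVector gaussian_blur3(NumericVector vol, IntegerVector dims,
                             double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int rad = (int)std::ceil(3 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + rad];
  }
  for (double& k : ker) k /= s;
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  auto reflect = [](int i, int n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
    return i;
  };
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        for (int o = -rad; o <= rad; ++o)
          acc += ker[o + rad] * a[reflect(i + o, nx) + nx * (j + (size_t)ny * k)];
        b[i + nx * (j + (size_t)ny * k)] = acc;
      }
  std::swap(a, b);
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        for (int o = -rad; o <= rad; ++o)
          acc += ker[o + rad] * a[i + nx * (reflect(j + o, ny) + (size_t)ny * k)];
        b[i + nx * (j + (size_t)ny * k)] = acc;
      }
  std::swap(a, b);
  // z pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        for (int o = -rad; o <= rad; ++o)
          acc += ker[o + rad] * a[i + nx * (j + (size_t)ny * reflect(k + o, nz))];
        b[i + nx * (j + (size_t)ny * k)] = acc;
      }
  return NumericVector(b.begin(), b.end());
}
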