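#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Separable squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// generalized to anisotropic voxel spacing. Input: logical mask; output:
// squared distance (in mm^2 if spacing is in mm) from each voxel to the
// nearest TRUE voxel. Voxels inside the mask get 0; an all-FALSE mask gives Inf.

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double step) {
  const double INF = std::numeric_limits<double>::infinity();
  const double s2 = step * step;
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;  // index of rightmost parabola in the lower envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;  // infinite parabolas never enter the envelope
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s = 0.0;
    bool restart = false;
    while (true) {
      s = ((f[q] + (double)q * q * s2) - (f[v[k]] + (double)v[k] * v[k] * s2)) /
          (2.0 * s2 * (q - v[k]));
      if (s <= z[k]) {
        --k;
        if (k < 0) {
          k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
          restart = true;
          break;
        }
      } else break;
    }
    if (restart) continue;
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  if (k < 0) {  // no finite source in this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double diff = (double)(q - v[kk]) * step;
    d[q] = diff * diff + f[v[kk]];
  }
}

// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x (fastest-varying)
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = g[base + (R_xlen_t)z * plane];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * plane] = d[z];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = g[i];
  out.attr("dim") = dim;
  return out;
}

// 26-connectivity connected-component labelling by breadth-first search.
// Returns integer labels (0 = background); components are numbered in
// decreasing voxel-count order (label 1 is the largest).

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> sizes;  // sizes[k] = size of component k+1
  std::queue<R_xlen_t> q;
  int next = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++next;
    R_xlen_t count = 0;
    lab[start] = next;
    q.push(start);
    while (!q.empty()) {
      R_xlen_t i = q.front(); q.pop();
      ++count;
      int z = (int)(i / plane);
      int rem = (int)(i % plane);
      int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            R_xlen_t j = (R_xlen_t)zz * plane + (R_xlen_t)yy * nx + xx;
            if (mask[j] && lab[j] == 0) { lab[j] = next; q.push(j); }
          }
        }
      }
    }
    sizes.push_back(count);
  }

  // renumber so label 1 is the largest component
  if (next > 1) {
    std::vector<int> order(next);
    for (int k = 0; k < next; ++k) order[k] = k;
    std::stable_sort(order.begin(), order.end(),
                     [&](int a, int b) { return sizes[a] > sizes[b]; });
    std::vector<int> remap(next + 1, 0);
    for (int r = 0; r < next; ++r) remap[order[r] + 1] = r + 1;
    for (R_xlen_t i = 0; i < n; ++i)
      if (lab[i] != 0) lab[i] = remap[lab[i]];
  }
  lab.attr("dim") = dim;
  return lab;
}
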