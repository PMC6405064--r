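#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// ---- 3D squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance of each foreground voxel to the nearest background voxel centre.

static void edt_1d(const std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// mask: integer/logical array (0 background, nonzero foreground), dims nx,ny,nz.
// Returns squared distances (voxel units) to nearest background voxel; the
// array is implicitly zero-padded outside its bounds (background all around).
// The pad enters each 1-d pass as sentinel parabola sites at virtual
// positions -1 and n with f = 0, so across-axis combinations stay exact.
// [[Rcpp::export]]
NumericVector edt3d_cpp(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t N = (R_xlen_t)nx * ny * nz;
  NumericVector out(N);
  const double INF = 1e18;
  for (R_xlen_t i = 0; i < N; ++i) out[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz)) + 2;
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // run edt_1d over n + 2 sites; extended position = real position + 1,
  // sentinels at extended 0 and n + 1 carry f = 0 (virtual background)
  // pass along x
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * zz);
      f[0] = 0.0; f[nx + 1] = 0.0;
      for (int x = 0; x < nx; ++x) f[x + 1] = out[base + x];
      edt_1d(f, d, v, z, nx + 2);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x + 1];
    }
  // pass along y
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * zz;
      f[0] = 0.0; f[ny + 1] = 0.0;
      for (int y = 0; y < ny; ++y) f[y + 1] = out[base + (R_xlen_t)nx * y];
      edt_1d(f, d, v, z, ny + 2);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nx * y] = d[y + 1];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      f[0] = 0.0; f[nz + 1] = 0.0;
      for (int zz = 0; zz < nz; ++zz) f[zz + 1] = out[base + stride * zz];
      edt_1d(f, d, v, z, nz + 2);
      for (int zz = 0; zz < nz; ++zz) out[base + stride * zz] = d[zz + 1];
    }
  return out;
}

// Hildebrand local thickness by inscribed-sphere propagation.
// r2: squared EDT distances (integer-valued doubles) on the mask, 0
// elsewhere. Propagates, to every mask voxel u, the largest r2(v) among
// spheres (center v, radius sqrt(r2(v))) that cover u; coverage is decided
// in exact integer squared-distance arithmetic. The R wrapper takes the
// square root and doubles it.
// [[Rcpp::export]]
NumericVector local_radius2_cpp(NumericVector r2, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t N = (R_xlen_t)nx * ny * nz;
  NumericVector out(N);
  // order voxels by decreasing radius so large spheres paint first
  std::vector<R_xlen_t> idx;
  idx.reserve(N / 8);
  for (R_xlen_t i = 0; i < N; ++i) if (r2[i] > 0) idx.push_back(i);
  std::sort(idx.begin(), idx.end(),
            [&](R_xlen_t a, R_xlen_t b) { return r2[a] > r2[b]; });
  for (R_xlen_t ii = 0; ii < (R_xlen_t)idx.size(); ++ii) {
    R_xlen_t i = idx[ii];
    double rr = r2[i];
    int x = (int)(i % nx);
    int y = (int)((i / nx) % ny);
    int zz = (int)(i / ((R_xlen_t)nx * ny));
    int ir = (int)std::floor(std::sqrt(rr) + 1e-9);
    for (int dz = -ir; dz <= ir; ++dz) {
      int z2 = zz + dz; if (z2 < 0 || z2 >= nz) continue;
      for (int dy = -ir; dy <= ir; ++dy) {
        int y2 = y + dy; if (y2 < 0 || y2 >= ny) continue;
        double dd = (double)dz * dz + (double)dy * dy;
        if (dd > rr) continue;
        int dxmax = (int)std::floor(std::sqrt(rr - dd) + 1e-9);
        R_xlen_t base = (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2);
        int x0 = std::max(0, x - dxmax), x1 = std::min(nx - 1, x + dxmax);
        for (int x2 = x0; x2 <= x1; ++x2) {
          R_xlen_t j = base + x2;
          if (r2[j] > 0 && out[j] < rr) out[j] = rr;
        }
      }
    }
  }
  return out;
}

// 26-connected component labelling of a binary 3D array.
// Returns integer labels (0 background, 1..k components).
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t N = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(N);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < N; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int zz = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        int z2 = zz + dz; if (z2 < 0 || z2 >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int y2 = y + dy; if (y2 < 0 || y2 >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x2 = x + dx; if (x2 < 0 || x2 >= nx) continue;
            R_xlen_t j = x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
    }
  }
  return lab;
}
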