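#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// Offsets for a 3-D neighbourhood. connectivity: 6 (faces) or 26 (full cube).
// For a single-slice volume (nz == 1) the 26-neighbourhood restricted to the
// plane is exactly 2-D 8-connectivity.
static void neighbour_offsets(int connectivity, std::vector<int>& dx,
                              std::vector<int>& dy, std::vector<int>& dz) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh > 1) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// Label connected components of a binary volume. Returns integer labels,
// 0 for background, 1..K for components (ordered by first voxel encountered).
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  IntegerVector labels(n, 0);
  int next_label = 0;
  std::vector<int> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    stack.push_back((int)i);
    labels[i] = next_label;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int z = cur / (nx * ny);
      int rem = cur - z * nx * ny;
      int y = rem / nx;
      int x = rem - y * nx;
      for (size_t k = 0; k < dx.size(); ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int j = xx + nx * (yy + ny * zz);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          stack.push_back(j);
        }
      }
    }
  }
  return labels;
}

// Breadth-first region growing from seed voxels: a voxel joins the region if
// it is 26-connected (or 6-) to an accepted voxel and its intensity exceeds
// the threshold (strict). Seeds below the threshold are inert.
// seeds are 0-based linear indices.
// [[Rcpp::export(name = ".cpp_region_grow")]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dims,
                              IntegerVector seeds, double threshold,
                              int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vol.size() != n) stop("volume length does not match dims");
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  LogicalVector grown(n, false);
  std::queue<int> q;
  for (R_xlen_t s = 0; s < seeds.size(); ++s) {
    int i = seeds[s];
    if (i < 0 || i >= n) stop("seed index out of range");
    if (!grown[i] && vol[i] > threshold) {
      grown[i] = true;
      q.push(i);
    }
  }
  while (!q.empty()) {
    int cur = q.front(); q.pop();
    int z = cur / (nx * ny);
    int rem = cur - z * nx * ny;
    int y = rem / nx;
    int x = rem - y * nx;
    for (size_t k = 0; k < dx.size(); ++k) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      int j = xx + nx * (yy + ny * zz);
      if (!grown[j] && vol[j] > threshold) {
        grown[j] = true;
        q.push(j);
      }
    }
  }
  return grown;
}

// One-dimensional squared-distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher). f: input squared distances, d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance transform: for every foreground voxel, the
// distance (voxel centre to voxel centre) to the nearest background voxel;
// 0 on background. Separable squared-distance passes along x, y, z.
// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims) {
  const double LARGE = 1e20;  // exceeds any attainable squared distance
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? LARGE : 0.0;

  std::vector<double> f, g;
  // pass along x
  f.resize(nx); g.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = d[base + x];
      dt1d(f, g, nx);
      for (int x = 0; x < nx; ++x) d[base + x] = g[x];
    }
  // pass along y
  f.resize(ny); g.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * z;
      for (int y = 0; y < ny; ++y) f[y] = d[base + (R_xlen_t)nx * y];
      dt1d(f, g, ny);
      for (int y = 0; y < ny; ++y) d[base + (R_xlen_t)nx * y] = g[y];
    }
  // pass along z
  f.resize(nz); g.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      for (int z = 0; z < nz; ++z) f[z] = d[base + (R_xlen_t)nx * ny * z];
      dt1d(f, g, nz);
      for (int z = 0; z < nz; ++z) d[base + (R_xlen_t)nx * ny * z] = g[z];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (d[i] >= 1e19) ? R_PosInf : std::sqrt(d[i]);
  return out;
}
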