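#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// 3D connected-component labelling of a binary volume by iterative BFS.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// Returns an integer volume; background = 0, components = 1..n.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int m = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int nnb = (int)dx.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  int current = 0;

  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++current;
    labels[seed] = current;
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int k = 0; k < nnb; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  labels.attr("n_components") = current;
  return labels;
}

// 1D squared-distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher.
static void dt1d(const double* f, double* d, int n,
                 std::vector<int>& v, std::vector<double>& zbuf) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  zbuf[0] = -INF;
  zbuf[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= zbuf[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in voxels) from every voxel to the nearest
// TRUE voxel of `sites`. Voxels with no reachable site get Inf (empty sites).
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector sites, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sites.size() != n) stop("sites length does not match dims");
  const double INF = std::numeric_limits<double>::infinity();

  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = sites[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      bool any = false;
      for (int x = 0; x < nx; ++x) { f[x] = g[base + x]; if (f[x] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), nx, v, zbuf);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      bool any = false;
      for (int y = 0; y < ny; ++y) { f[y] = g[base + (R_xlen_t)y * nx]; if (f[y] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), ny, v, zbuf);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      bool any = false;
      for (int z = 0; z < nz; ++z) { f[z] = g[base + (R_xlen_t)z * nxy]; if (f[z] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), nz, v, zbuf);
      for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * nxy] = d[z];
    }

  g.attr("dim") = dims;
  return g;
}

// Per-label voxel counts for an integer label volume (labels 1..n_labels).
// [[Rcpp::export(name = ".label_counts_cpp")]]
NumericVector label_counts_cpp(IntegerVector labels, int n_labels) {
  NumericVector counts(n_labels);
  const R_xlen_t n = labels.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int l = labels[i];
    if (l > 0 && l <= n_labels) counts[l - 1] += 1.0;
  }
  return counts;
}
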