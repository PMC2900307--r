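#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform with anisotropic sampling
// (Felzenszwalb & Huttenlocher separable lower-envelope algorithm,
// run once per axis with the physical voxel spacing as sample step).

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform of sampled function f at positions q*w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  std::vector<int> v(n);      // parabola sites
  std::vector<double> z(n + 1); // boundaries between parabolas (physical units)
  int k = -1;
  for (int q = 0; q < n; q++) {
    if (f[q] == INF) continue;
    double xq = q * w;
    double s = 0.0;
    while (k >= 0) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) k--; else break;
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; }
    else { k++; v[k] = q; z[k] = s; z[k + 1] = INF; }
  }
  if (k < 0) { // no finite sample
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * w;
    while (z[j + 1] < xq) j++;
    double dx = xq - v[j] * w;
    d[q] = dx * dx + f[v[j]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector feature, int nx, int ny, int nz,
                      double sx, double sy, double sz) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = feature[i] ? 0.0 : INF;

  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++) {
        R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int x = 0; x < nx; x++) f[x] = out[base + x];
        dt1d(f, d, nx, sx);
        for (int x = 0; x < nx; x++) out[base + x] = d[x];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int z = 0; z < nz; z++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t base = x + (R_xlen_t)nx * ny * z;
        for (int y = 0; y < ny; y++) f[y] = out[base + (R_xlen_t)nx * y];
        dt1d(f, d, ny, sy);
        for (int y = 0; y < ny; y++) out[base + (R_xlen_t)nx * y] = d[y];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t base = x + (R_xlen_t)nx * y;
        for (int z = 0; z < nz; z++) f[z] = out[base + (R_xlen_t)nx * ny * z];
        dt1d(f, d, nz, sz);
        for (int z = 0; z < nz; z++) out[base + (R_xlen_t)nx * ny * z] = d[z];
      }
  }
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (out[i] == INF) ? R_PosInf : std::sqrt(out[i]);
  return out;
}
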