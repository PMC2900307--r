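#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <numeric>
#include <functional>
using namespace Rcpp;

// Grayscale area opening (Meijster & Wilkinson union-find formulation):
// removes bright structures whose flat-zone area at any level is below
// `lambda` voxels. Used for the top-hat-by-size background estimate.

// [[Rcpp::export]]
NumericVector cpp_area_opening(NumericVector img, int nx, int ny, int nz,
                               int lambda, int conn) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (lambda <= 1) return clone(img);
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; cz++)
    for (int cy = -1; cy <= 1; cy++)
      for (int cx = -1; cx <= 1; cx++) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        if (conn == 6 && std::abs(cx) + std::abs(cy) + std::abs(cz) > 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  int nn = (int)dx.size();

  std::vector<R_xlen_t> order(n);
  std::iota(order.begin(), order.end(), (R_xlen_t)0);
  std::stable_sort(order.begin(), order.end(),
                   [&](R_xlen_t a, R_xlen_t b) { return img[a] > img[b]; });
  std::vector<R_xlen_t> rank(n);
  for (R_xlen_t i = 0; i < n; i++) rank[order[i]] = i;

  const R_xlen_t INACTIVE = -1;
  std::vector<R_xlen_t> parent(n, INACTIVE);
  std::vector<R_xlen_t> area(n, 0);

  std::function<R_xlen_t(R_xlen_t)> find = [&](R_xlen_t p) {
    R_xlen_t r = p;
    while (parent[r] != r) r = parent[r];
    while (parent[p] != r) { R_xlen_t t = parent[p]; parent[p] = r; p = t; }
    return r;
  };

  for (R_xlen_t i = 0; i < n; i++) {
    R_xlen_t p = order[i];
    parent[p] = p;
    area[p] = 1;
    int x = (int)(p % nx);
    int y = (int)((p / nx) % ny);
    int z = (int)(p / ((R_xlen_t)nx * ny));
    for (int q = 0; q < nn; q++) {
      int X = x + dx[q], Y = y + dy[q], Z = z + dz[q];
      if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
      R_xlen_t j = X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z);
      if (parent[j] == INACTIVE) continue; // not yet processed
      R_xlen_t r = find(j);
      if (r == p) continue;
      if (img[r] == img[p] || area[r] < lambda) {
        parent[r] = p;
        area[p] += area[r];
      } else {
        area[p] = lambda; // touches a settled brighter component
      }
    }
  }
  NumericVector out(n);
  for (R_xlen_t i = n - 1; i >= 0; i--) {
    R_xlen_t p = order[i];
    if (parent[p] == p) out[p] = img[p];
    else out[p] = out[parent[p]];
    if (i == 0) break;
  }
  return out;
}
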