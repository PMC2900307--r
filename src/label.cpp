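#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling (6- or 26-connectivity), scan-order labels.

static inline void neighbor_offsets(int conn, int nx, int ny,
                                    std::vector<int>& dx, std::vector<int>& dy,
                                    std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int cz = -1; cz <= 1; cz++)
    for (int cy = -1; cy <= 1; cy++)
      for (int cx = -1; cx <= 1; cx++) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (conn == 6 && manh > 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, int nx, int ny, int nz, int conn) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz;
  neighbor_offsets(conn, nx, ny, dx, dy, dz);
  int nn = (int)dx.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i]) continue;
    next++;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int x = (int)(p % nx);
      int y = (int)((p / nx) % ny);
      int z = (int)(p / ((R_xlen_t)nx * ny));
      for (int q = 0; q < nn; q++) {
        int X = x + dx[q], Y = y + dy[q], Z = z + dz[q];
        if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
        R_xlen_t j = X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z);
        if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}
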