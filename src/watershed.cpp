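#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Seeded watershed (priority flood), regional extrema, and grayscale
// reconstruction by dilation on 3D arrays.

struct QItem {
  double prio;
  unsigned long order;
  R_xlen_t idx;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.prio != b.prio) return a.prio > b.prio; // min-heap on priority
    return a.order > b.order;                     // FIFO tie-break
  }
};

static void offsets(int conn, std::vector<int>& dx, std::vector<int>& dy,
                    std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int cz = -1; cz <= 1; cz++)
    for (int cy = -1; cy <= 1; cy++)
      for (int cx = -1; cx <= 1; cx++) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        if (conn == 6 && std::abs(cx) + std::abs(cy) + std::abs(cz) > 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
}

// Flood from labeled seeds over `priority` (lower floods first), within mask.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector seeds,
                            LogicalVector mask, int nx, int ny, int nz,
                            int conn) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dx, dy, dz;
  offsets(conn, dx, dy, dz);
  int nn = (int)dx.size();
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  unsigned long counter = 0;
  for (R_xlen_t i = 0; i < n; i++)
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push({priority[i], counter++, i});
    }
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    R_xlen_t p = it.idx;
    int x = (int)(p % nx);
    int y = (int)((p / nx) % ny);
    int z = (int)(p / ((R_xlen_t)nx * ny));
    for (int q = 0; q < nn; q++) {
      int X = x + dx[q], Y = y + dy[q], Z = z + dz[q];
      if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
      R_xlen_t j = X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z);
      if (!mask[j] || lab[j]) continue;
      lab[j] = lab[p];
      pq.push({priority[j], counter++, j});
    }
  }
  return lab;
}

// Label regional maxima plateaus of img within mask (neighbors outside the
// mask are ignored). Pass -img for regional minima.
// [[Rcpp::export]]
IntegerVector cpp_regional_maxima(NumericVector img, LogicalVector mask,
                                  int nx, int ny, int nz, int conn) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<signed char> state(n, 0); // 0 unseen, 1 in plateau queue, 2 done
  std::vector<int> dx, dy, dz;
  offsets(conn, dx, dy, dz);
  int nn = (int)dx.size();
  std::vector<R_xlen_t> plateau, stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || state[i]) continue;
    double v = img[i];
    bool is_max = true;
    plateau.clear();
    stack.clear();
    stack.push_back(i);
    state[i] = 1;
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      plateau.push_back(p);
      int x = (int)(p % nx);
      int y = (int)((p / nx) % ny);
      int z = (int)(p / ((R_xlen_t)nx * ny));
      for (int q = 0; q < nn; q++) {
        int X = x + dx[q], Y = y + dy[q], Z = z + dz[q];
        if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
        R_xlen_t j = X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z);
        if (!mask[j]) continue;
        if (img[j] > v) is_max = false;
        else if (img[j] == v && state[j] == 0) {
          state[j] = 1;
          stack.push_back(j);
        }
      }
    }
    int value = 0;
    if (is_max) { next++; value = next; }
    for (size_t q = 0; q < plateau.size(); q++) {
      lab[plateau[q]] = value;
      state[plateau[q]] = 2;
    }
  }
  return lab;
}

// Grayscale reconstruction by dilation of `marker` under `ceiling`
// (marker <= ceiling pointwise). Hybrid raster/FIFO algorithm.
// [[Rcpp::export]]
NumericVector cpp_reconstruct(NumericVector marker, NumericVector ceiling,
                              int nx, int ny, int nz, int conn) {
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector J(n);
  for (R_xlen_t i = 0; i < n; i++) J[i] = std::min(marker[i], ceiling[i]);
  std::vector<int> dx, dy, dz;
  offsets(conn, dx, dy, dz);
  int nn = (int)dx.size();
  // split neighborhood into causal (raster-earlier) and anti-causal halves
  std::vector<int> plus, minus;
  for (int q = 0; q < nn; q++) {
    R_xlen_t off = dx[q] + (R_xlen_t)nx * (dy[q] + (R_xlen_t)ny * dz[q]);
    if (off < 0) minus.push_back(q); else plus.push_back(q);
  }
  auto idx_ok = [&](int X, int Y, int Z) {
    return X >= 0 && Y >= 0 && Z >= 0 && X < nx && Y < ny && Z < nz;
  };
  // forward scan
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t p = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        double m = J[p];
        for (size_t t = 0; t < minus.size(); t++) {
          int q = minus[t];
          if (!idx_ok(x + dx[q], y + dy[q], z + dz[q])) continue;
          R_xlen_t j = p + dx[q] + (R_xlen_t)nx * (dy[q] + (R_xlen_t)ny * dz[q]);
          if (J[j] > m) m = J[j];
        }
        J[p] = std::min(m, ceiling[p]);
      }
  // backward scan + queue init
  std::queue<R_xlen_t> fifo;
  for (int z = nz - 1; z >= 0; z--)
    for (int y = ny - 1; y >= 0; y--)
      for (int x = nx - 1; x >= 0; x--) {
        R_xlen_t p = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        double m = J[p];
        for (size_t t = 0; t < plus.size(); t++) {
          int q = plus[t];
          if (!idx_ok(x + dx[q], y + dy[q], z + dz[q])) continue;
          R_xlen_t j = p + dx[q] + (R_xlen_t)nx * (dy[q] + (R_xlen_t)ny * dz[q]);
          if (J[j] > m) m = J[j];
        }
        m = std::min(m, ceiling[p]);
        J[p] = m;
        for (size_t t = 0; t < plus.size(); t++) {
          int q = plus[t];
          if (!idx_ok(x + dx[q], y + dy[q], z + dz[q])) continue;
          R_xlen_t j = p + dx[q] + (R_xlen_t)nx * (dy[q] + (R_xlen_t)ny * dz[q]);
          if (J[j] < m && J[j] < ceiling[j]) { fifo.push(p); break; }
        }
      }
  while (!fifo.empty()) {
    R_xlen_t p = fifo.front(); fifo.pop();
    int x = (int)(p % nx);
    int y = (int)((p / nx) % ny);
    int z = (int)(p / ((R_xlen_t)nx * ny));
    for (int q = 0; q < nn; q++) {
      int X = x + dx[q], Y = y + dy[q], Z = z + dz[q];
      if (!idx_ok(X, Y, Z)) continue;
      R_xlen_t j = X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z);
      if (J[j] < J[p] && J[j] < ceiling[j]) {
        J[j] = std::min(J[p], ceiling[j]);
        fifo.push(j);
      }
    }
  }
  return J;
}
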