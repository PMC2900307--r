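#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Distance kernels for the empty-space (F) and nearest-neighbor (G)
// functions and the Monte-Carlo reference batches. All coordinates are in
// physical units (micrometres); matrices are n x 3.

static inline double min_dist2_to(const double* px, const double* py,
                                  const double* pz, int k,
                                  double x, double y, double z) {
  double best = R_PosInf;
  for (int j = 0; j < k; j++) {
    double dx = x - px[j], dy = y - py[j], dz = z - pz[j];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < best) best = d2;
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix eval, NumericMatrix pts) {
  int ne = eval.nrow(), k = pts.nrow();
  std::vector<double> px(k), py(k), pz(k);
  for (int j = 0; j < k; j++) {
    px[j] = pts(j, 0); py[j] = pts(j, 1); pz[j] = pts(j, 2);
  }
  NumericVector out(ne);
  for (int i = 0; i < ne; i++)
    out[i] = std::sqrt(min_dist2_to(px.data(), py.data(), pz.data(), k,
                                    eval(i, 0), eval(i, 1), eval(i, 2)));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_nn_dists(NumericMatrix pts) {
  int k = pts.nrow();
  NumericVector out(k);
  for (int i = 0; i < k; i++) {
    double best = R_PosInf;
    for (int j = 0; j < k; j++) {
      if (i == j) continue;
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

static inline void bin_cumulative(const std::vector<double>& d2, double dr,
                                  int ngrid, double* row) {
  std::vector<int> counts(ngrid + 1, 0);
  for (size_t i = 0; i < d2.size(); i++) {
    double d = std::sqrt(d2[i]);
    int b = (int)std::ceil(d / dr);
    if (b < 1) b = 1;
    if (b > ngrid) b = ngrid;
    counts[b]++;
  }
  int acc = 0;
  for (int b = 1; b <= ngrid; b++) {
    acc += counts[b];
    row[b - 1] = acc;
  }
}

// Cumulative counts of distance samples on the grid dr, 2*dr, ..., ngrid*dr.
// kind 0 = F (empty-space distances from eval points), 1 = G (NN distances).
// [[Rcpp::export]]
NumericVector cpp_gf_counts(NumericMatrix pts, NumericMatrix eval, int kind,
                            double dr, int ngrid) {
  int k = pts.nrow();
  std::vector<double> d2;
  if (kind == 0) {
    int ne = eval.nrow();
    std::vector<double> px(k), py(k), pz(k);
    for (int j = 0; j < k; j++) {
      px[j] = pts(j, 0); py[j] = pts(j, 1); pz[j] = pts(j, 2);
    }
    d2.resize(ne);
    for (int i = 0; i < ne; i++)
      d2[i] = min_dist2_to(px.data(), py.data(), pz.data(), k,
                           eval(i, 0), eval(i, 1), eval(i, 2));
  } else {
    d2.resize(k);
    for (int i = 0; i < k; i++) {
      double best = R_PosInf;
      for (int j = 0; j < k; j++) {
        if (i == j) continue;
        double dx = pts(i, 0) - pts(j, 0);
        double dy = pts(i, 1) - pts(j, 1);
        double dz = pts(i, 2) - pts(j, 2);
        double v = dx * dx + dy * dy + dz * dz;
        if (v < best) best = v;
      }
      d2[i] = best;
    }
  }
  NumericVector out(ngrid);
  bin_cumulative(d2, dr, ngrid, REAL(out));
  return out;
}

// Simulate P completely random binomial patterns of k points in the voxelized
// domain given by fg (n x 3 voxel centers) and return the P x ngrid matrix of
// cumulative distance counts (F against shared eval points, or G). Uses R's
// RNG stream, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix cpp_gf_null_batch(NumericMatrix fg, double sx, double sy,
                                double sz, int k, int P, NumericMatrix eval,
                                int kind, double dr, int ngrid) {
  int nfg = fg.nrow();
  int ne = eval.nrow();
  NumericMatrix out(P, ngrid);
  std::vector<double> px(k), py(k), pz(k), d2;
  std::vector<double> row(ngrid);
  const double* ex = (ne > 0) ? &eval(0, 0) : nullptr;
  const double* ey = (ne > 0) ? &eval(0, 1) : nullptr;
  const double* ez = (ne > 0) ? &eval(0, 2) : nullptr;
  RNGScope scope;
  for (int p = 0; p < P; p++) {
    for (int j = 0; j < k; j++) {
      int idx = (int)(unif_rand() * nfg);
      if (idx >= nfg) idx = nfg - 1;
      px[j] = fg(idx, 0) + (unif_rand() - 0.5) * sx;
      py[j] = fg(idx, 1) + (unif_rand() - 0.5) * sy;
      pz[j] = fg(idx, 2) + (unif_rand() - 0.5) * sz;
    }
    if (kind == 0) {
      d2.resize(ne);
      for (int i = 0; i < ne; i++)
        d2[i] = min_dist2_to(px.data(), py.data(), pz.data(), k,
                             ex[i], ey[i], ez[i]);
    } else {
      d2.resize(k);
      for (int i = 0; i < k; i++) {
        double best = R_PosInf;
        for (int j = 0; j < k; j++) {
          if (i == j) continue;
          double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
          double v = dx * dx + dy * dy + dz * dz;
          if (v < best) best = v;
        }
        d2[i] = best;
      }
    }
    bin_cumulative(d2, dr, ngrid, row.data());
    for (int b = 0; b < ngrid; b++) out(p, b) = row[b];
  }
  return out;
}
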