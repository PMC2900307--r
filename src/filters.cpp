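#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Rank and separable linear filtering on 3D arrays (column-major, x fastest).

// [[Rcpp::export]]
NumericVector cpp_median_filter(NumericVector img, int nx, int ny, int nz,
                                int radius) {
  if (radius <= 0) return clone(img);
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1) * (2 * radius + 1));
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        buf.clear();
        for (int cz = std::max(0, z - radius); cz <= std::min(nz - 1, z + radius); cz++)
          for (int cy = std::max(0, y - radius); cy <= std::min(ny - 1, y + radius); cy++)
            for (int cx = std::max(0, x - radius); cx <= std::min(nx - 1, x + radius); cx++)
              buf.push_back(img[cx + (R_xlen_t)nx * (cy + (R_xlen_t)ny * cz)]);
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + m);
          med = 0.5 * (med + lo);
        }
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = med;
      }
  return out;
}

// Convolve along one axis (0 = x, 1 = y, 2 = z) with mirror boundary.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector img, int nx, int ny, int nz,
                                NumericVector kernel, int axis) {
  int klen = kernel.size();
  int kh = klen / 2;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  R_xlen_t stride = (axis == 0) ? 1 :
                    (axis == 1) ? (R_xlen_t)nx : (R_xlen_t)nx * ny;
  // iterate over all lines along the chosen axis
  int d1 = (axis == 0) ? ny : nx;
  int d2 = (axis == 2) ? ny : nz;
  std::vector<double> line(len);
  for (int b = 0; b < d2; b++)
    for (int a = 0; a < d1; a++) {
      R_xlen_t base;
      if (axis == 0)      base = (R_xlen_t)nx * (a + (R_xlen_t)ny * b);
      else if (axis == 1) base = a + (R_xlen_t)nx * ny * b;
      else                base = a + (R_xlen_t)nx * b;
      for (int i = 0; i < len; i++) line[i] = img[base + stride * i];
      for (int i = 0; i < len; i++) {
        double acc = 0.0;
        for (int k = 0; k < klen; k++) {
          int j = i + k - kh;
          if (j < 0) j = -j - 1;            // mirror
          if (j >= len) j = 2 * len - j - 1;
          if (j < 0) j = 0;                  // tiny-axis guard
          if (j >= len) j = len - 1;
          acc += line[j] * kernel[k];
        }
        out[base + stride * i] = acc;
      }
    }
  return out;
}
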