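#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra (each grid cell split into
// six tetrahedra sharing the main diagonal). Vertices lie on cell edges at
// the linear interpolation of the iso level and are welded across cells via
// their edge key, so the resulting triangulation of a level set that does
// not touch the array border is closed (watertight).

static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};
static const int CORNER[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}
};

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector vol, int nx, int ny, int nz,
                        double iso, double sx, double sy, double sz) {
  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> verts; // x,y,z triples (physical units)
  std::vector<int> tris;     // 1-based vertex indices

  double spacing[3] = {sx, sy, sz};
  auto val = [&](int x, int y, int z) {
    return vol[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
  };
  auto edge_vertex = [&](R_xlen_t ga, R_xlen_t gb, double fa, double fb,
                         int ax, int ay, int az, int bx, int by, int bz) {
    uint64_t key = (ga < gb)
      ? ((uint64_t)ga << 32) | (uint64_t)gb
      : ((uint64_t)gb << 32) | (uint64_t)ga;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = (fb == fa) ? 0.5 : (iso - fa) / (fb - fa);
    double p[3] = {
      (ax + t * (bx - ax) + 0.5) * spacing[0],
      (ay + t * (by - ay) + 0.5) * spacing[1],
      (az + t * (bz - az) + 0.5) * spacing[2]
    };
    verts.push_back(p[0]); verts.push_back(p[1]); verts.push_back(p[2]);
    int id = (int)(verts.size() / 3);
    vmap[key] = id;
    return id;
  };

  int cx[8], cy[8], cz[8];
  double f[8];
  R_xlen_t g[8];
  for (int z = 0; z < nz - 1; z++)
    for (int y = 0; y < ny - 1; y++)
      for (int x = 0; x < nx - 1; x++) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; c++) {
          cx[c] = x + CORNER[c][0];
          cy[c] = y + CORNER[c][1];
          cz[c] = z + CORNER[c][2];
          g[c] = cx[c] + (R_xlen_t)nx * (cy[c] + (R_xlen_t)ny * cz[c]);
          f[c] = val(cx[c], cy[c], cz[c]);
          if (f[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; t++) {
          const int* T = TETS[t];
          int inside[4], nin = 0;
          for (int c = 0; c < 4; c++)
            if (f[T[c]] > iso) inside[nin++] = c;
          if (nin == 0 || nin == 4) continue;
          int iv[4], ov[4], no = 0, ni = 0;
          for (int c = 0; c < 4; c++) {
            if (f[T[c]] > iso) iv[ni++] = T[c]; else ov[no++] = T[c];
          }
          auto EV = [&](int a, int b) {
            return edge_vertex(g[a], g[b], f[a], f[b],
                               cx[a], cy[a], cz[a], cx[b], cy[b], cz[b]);
          };
          if (ni == 1) {
            int v0 = EV(iv[0], ov[0]), v1 = EV(iv[0], ov[1]), v2 = EV(iv[0], ov[2]);
            tris.push_back(v0); tris.push_back(v1); tris.push_back(v2);
          } else if (ni == 3) {
            int v0 = EV(ov[0], iv[0]), v1 = EV(ov[0], iv[1]), v2 = EV(ov[0], iv[2]);
            tris.push_back(v0); tris.push_back(v1); tris.push_back(v2);
          } else { // ni == 2: quad -> two triangles
            int a0 = EV(iv[0], ov[0]), a1 = EV(iv[0], ov[1]);
            int b0 = EV(iv[1], ov[0]), b1 = EV(iv[1], ov[1]);
            tris.push_back(a0); tris.push_back(a1); tris.push_back(b1);
            tris.push_back(a0); tris.push_back(b1); tris.push_back(b0);
          }
        }
      }

  int nv = (int)(verts.size() / 3);
  int nt = (int)(tris.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nt, 3);
  for (int i = 0; i < nv; i++) {
    V(i, 0) = verts[3 * i];
    V(i, 1) = verts[3 * i + 1];
    V(i, 2) = verts[3 * i + 2];
  }
  for (int i = 0; i < nt; i++) {
    F(i, 0) = tris[3 * i];
    F(i, 1) = tris[3 * i + 1];
    F(i, 2) = tris[3 * i + 2];
  }
  return List::create(Named("vertices") = V, Named("faces") = F);
}
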