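#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Marching tetrahedra on the voxel lattice. Each cube of 8 voxel centers is
// split into 6 tetrahedra sharing the main diagonal; triangle vertices are
// linear interpolations along tet edges. Triangles are oriented so the normal
// points away from the f > level side (outward for a cell with rho = 1 inside).

static const int TETS[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
};
// cube corner offsets (x, y, z)
static const int CORN[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

struct V3 { double x, y, z; };

static inline V3 interp(double level, const V3& a, const V3& b,
                        double fa, double fb) {
  double t = (level - fa) / (fb - fa);
  V3 o;
  o.x = a.x + t * (b.x - a.x);
  o.y = a.y + t * (b.y - a.y);
  o.z = a.z + t * (b.z - a.z);
  return o;
}

// [[Rcpp::export]]
List cpp_isosurface(NumericVector f, double level, double h) {
  IntegerVector d = f.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  const double* p = f.begin();
  std::vector<double> vx, vy, vz;

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        double fc[8]; V3 pc[8];
        for (int c = 0; c < 8; ++c) {
          int ii = i + CORN[c][0], jj = j + CORN[c][1], kc = k + CORN[c][2];
          fc[c] = p[ii + nx * (jj + (R_xlen_t)ny * kc)];
          pc[c].x = (ii + 0.5) * h;
          pc[c].y = (jj + 0.5) * h;
          pc[c].z = (kc + 0.5) * h;
        }
        for (int t = 0; t < 6; ++t) {
          const int* tv = TETS[t];
          double tf[4]; V3 tp[4];
          int above = 0;
          for (int c = 0; c < 4; ++c) {
            tf[c] = fc[tv[c]]; tp[c] = pc[tv[c]];
            if (tf[c] > level) ++above;
          }
          if (above == 0 || above == 4) continue;
          int hi[4], lo[4], nh = 0, nl = 0;
          for (int c = 0; c < 4; ++c) {
            if (tf[c] > level) hi[nh++] = c; else lo[nl++] = c;
          }
          V3 tri[6]; int ntri = 0;
          if (nh == 1) {
            // one vertex above: single triangle
            tri[0] = interp(level, tp[hi[0]], tp[lo[0]], tf[hi[0]], tf[lo[0]]);
            tri[1] = interp(level, tp[hi[0]], tp[lo[1]], tf[hi[0]], tf[lo[1]]);
            tri[2] = interp(level, tp[hi[0]], tp[lo[2]], tf[hi[0]], tf[lo[2]]);
            ntri = 1;
          } else if (nh == 3) {
            tri[0] = interp(level, tp[lo[0]], tp[hi[0]], tf[lo[0]], tf[hi[0]]);
            tri[1] = interp(level, tp[lo[0]], tp[hi[1]], tf[lo[0]], tf[hi[1]]);
            tri[2] = interp(level, tp[lo[0]], tp[hi[2]], tf[lo[0]], tf[hi[2]]);
            ntri = 1;
          } else {
            // two above, two below: quad split into two triangles
            V3 q0 = interp(level, tp[hi[0]], tp[lo[0]], tf[hi[0]], tf[lo[0]]);
            V3 q1 = interp(level, tp[hi[0]], tp[lo[1]], tf[hi[0]], tf[lo[1]]);
            V3 q2 = interp(level, tp[hi[1]], tp[lo[1]], tf[hi[1]], tf[lo[1]]);
            V3 q3 = interp(level, tp[hi[1]], tp[lo[0]], tf[hi[1]], tf[lo[0]]);
            tri[0] = q0; tri[1] = q1; tri[2] = q2;
            tri[3] = q0; tri[4] = q2; tri[5] = q3;
            ntri = 2;
          }
          // mean position of the "above" (inside) tet vertices
          double mx = 0, my = 0, mz = 0;
          for (int c = 0; c < nh; ++c) {
            mx += tp[hi[c]].x; my += tp[hi[c]].y; mz += tp[hi[c]].z;
          }
          mx /= nh; my /= nh; mz /= nh;
          for (int q = 0; q < ntri; ++q) {
            V3 a = tri[3 * q], b = tri[3 * q + 1], c3 = tri[3 * q + 2];
            double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
            double wx = c3.x - a.x, wy = c3.y - a.y, wz = c3.z - a.z;
            double nxv = uy * wz - uz * wy;
            double nyv = uz * wx - ux * wz;
            double nzv = ux * wy - uy * wx;
            double cx = (a.x + b.x + c3.x) / 3.0 - mx;
            double cy = (a.y + b.y + c3.y) / 3.0 - my;
            double cz = (a.z + b.z + c3.z) / 3.0 - mz;
            bool flip = (nxv * cx + nyv * cy + nzv * cz) < 0;
            if (flip) { V3 tmp = b; b = c3; c3 = tmp; }
            vx.push_back(a.x); vy.push_back(a.y); vz.push_back(a.z);
            vx.push_back(b.x); vy.push_back(b.y); vz.push_back(b.z);
            vx.push_back(c3.x); vy.push_back(c3.y); vz.push_back(c3.z);
          }
        }
      }

  int ntri = (int)(vx.size() / 3);
  NumericMatrix verts(3 * ntri, 3);
  for (int t = 0; t < 3 * ntri; ++t) {
    verts(t, 0) = vx[t]; verts(t, 1) = vy[t]; verts(t, 2) = vz[t];
  }
  IntegerMatrix tris(ntri, 3);
  for (int t = 0; t < ntri; ++t) {
    tris(t, 0) = 3 * t + 1; tris(t, 1) = 3 * t + 2; tris(t, 2) = 3 * t + 3;
  }
  return List::create(_["vertices"] = verts, _["triangles"] = tris);
}

// Trilinear sampling of a 3D field at world coordinates (voxel centers at
// (index + 0.5) * h, 0-based), clamped at the domain boundary.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector f, NumericMatrix pts, double h) {
  IntegerVector d = f.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  const double* p = f.begin();
  int n = pts.nrow();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double x = pts(q, 0) / h - 0.5;
    double y = pts(q, 1) / h - 0.5;
    double z = pts(q, 2) / h - 0.5;
    int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
    double fx = x - i, fy = y - j, fz = z - k;
    if (i < 0) { i = 0; fx = 0; } if (i > nx - 2) { i = nx - 2; fx = 1; }
    if (j < 0) { j = 0; fy = 0; } if (j > ny - 2) { j = ny - 2; fy = 1; }
    if (k < 0) { k = 0; fz = 0; } if (k > nz - 2) { k = nz - 2; fz = 1; }
    double acc = 0.0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                     (dz ? fz : 1 - fz);
          acc += w * p[(i + dx) + nx * ((j + dy) + (R_xlen_t)ny * (k + dz))];
        }
    out[q] = acc;
  }
  return out;
}
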