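// Low-level 3D voxel primitives. Arrays are R arrays with dim = c(nz, ny, nx)
// (axis order z, y, x; column-major, so linear index = z + nz*(y + ny*nx_x)).
// Spacing vectors are physical voxel sizes (dz, dy, dx) in micrometres.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// ---------------------------------------------------------------- gaussian --

// Separable Gaussian blur with reflected boundaries; sigma in voxels per axis
// (order z, y, x). sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector vol, IntegerVector dims,
                             NumericVector sigma) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  int n[3] = {nz, ny, nx};
  // strides for walking along each axis in the flat array
  long strides[3] = {1, (long)nz, (long)nz * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (s * s));
      ksum += k[i + r];
    }
    for (double &kv : k) kv /= ksum;
    int len = n[ax];
    long stride = strides[ax];
    // iterate over all lines along axis ax
    long nlines = (long)nz * ny * nx / len;
    int o1 = (ax + 1) % 3, o2 = (ax + 2) % 3;
    for (long ln = 0; ln < nlines; ++ln) {
      long i1 = ln % n[o1], i2 = ln / n[o1];
      long base = i1 * strides[o1] + i2 * strides[o2];
      for (int p = 0; p < len; ++p) {
        double acc = 0;
        for (int i = -r; i <= r; ++i) {
          int q = p + i;
          if (q < 0) q = -q - 1;            // reflect
          if (q >= len) q = 2 * len - q - 1;
          acc += k[i + r] * a[base + (long)q * stride];
        }
        b[base + (long)p * stride] = acc;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// ------------------------------------------------------ connected components

// Label connected components of a binary mask; connectivity 6 or 26.
// Labels are assigned in scan order (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims,
                        int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long n = (long)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> dz, dy, dx;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cz == 0 && cy == 0 && cx == 0) continue;
        int manh = std::abs(cz) + std::abs(cy) + std::abs(cx);
        if (connectivity == 6 && manh > 1) continue;
        dz.push_back(cz); dy.push_back(cy); dx.push_back(cx);
      }
  int nextlab = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++nextlab;
    stack.clear();
    stack.push_back(s);
    lab[s] = nextlab;
    while (!stack.empty()) {
      long cur = stack.back(); stack.pop_back();
      int z = cur % nz, y = (cur / nz) % ny, x = cur / ((long)nz * ny);
      for (size_t k = 0; k < dz.size(); ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        long nb = idx3(zz, yy, xx, nz, ny);
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] = nextlab;
          stack.push_back(nb);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// --------------------------------------------------- distance transform ----

// 1D lower-envelope squared distance transform (Felzenszwalb & Huttenlocher)
// with physical sample spacing h.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 int n, double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double qq = (double)q * h, vv = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * h;
    while (z[k + 1] < qq) ++k;
    double diff = qq - (double)v[k] * h;
    d[q] = diff * diff + f[v[k]];
  }
}

// Squared Euclidean distance (physical units) from each foreground voxel to
// the nearest background voxel centre; 0 on background. spacing = (dz,dy,dx).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dims,
                         NumericVector spacing) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long n = (long)nz * ny * nx;
  const double INF = 1e30;
  std::vector<double> a(n);
  for (long i = 0; i < n; ++i) a[i] = fg[i] ? INF : 0.0;
  int dimn[3] = {nz, ny, nx};
  long strides[3] = {1, (long)nz, (long)nz * ny};
  for (int ax = 0; ax < 3; ++ax) {
    int len = dimn[ax];
    long stride = strides[ax];
    int o1 = (ax + 1) % 3, o2 = (ax + 2) % 3;
    long nlines = n / len;
    std::vector<double> f(len), d(len);
    for (long ln = 0; ln < nlines; ++ln) {
      long i1 = ln % dimn[o1], i2 = ln / dimn[o1];
      long base = i1 * strides[o1] + i2 * strides[o2];
      for (int p = 0; p < len; ++p) f[p] = a[base + (long)p * stride];
      dt1d(f, d, len, spacing[ax]);
      for (int p = 0; p < len; ++p) a[base + (long)p * stride] = d[p];
    }
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// ----------------------------------------------------------- watershed -----

struct WsNode {
  double pri;
  long ord;   // insertion order: deterministic FIFO tie-break
  long idx;
  int lab;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.pri != b.pri) return a.pri < b.pri;  // max-heap on priority
    return a.ord > b.ord;                      // then FIFO
  }
};

// Seeded watershed by priority flooding: grow seed labels outward in order of
// decreasing priority (e.g. a distance transform), restricted to mask.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority_, IntegerVector seeds,
                            LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long n = (long)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long ord = 0;
  for (long i = 0; i < n; ++i) {
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push({priority_[i], ord++, i, seeds[i]});
    }
  }
  static const int dz[6] = {1, -1, 0, 0, 0, 0};
  static const int dy[6] = {0, 0, 1, -1, 0, 0};
  static const int dx[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int z = nd.idx % nz, y = (nd.idx / nz) % ny, x = nd.idx / ((long)nz * ny);
    for (int k = 0; k < 6; ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      long nb = idx3(zz, yy, xx, nz, ny);
      if (mask[nb] && lab[nb] == 0) {
        lab[nb] = nd.lab;
        pq.push({priority_[nb], ord++, nb, nd.lab});
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ------------------------------------------------------ iso-surface area ---

static inline void lerp3(const double *a, const double *b, double fa,
                         double fb, double iso, double *out) {
  double t = (iso - fa) / (fb - fa);
  for (int i = 0; i < 3; ++i) out[i] = a[i] + t * (b[i] - a[i]);
}

static inline double triarea(const double *p, const double *q,
                             const double *r) {
  double u[3], v[3], c[3];
  for (int i = 0; i < 3; ++i) { u[i] = q[i] - p[i]; v[i] = r[i] - p[i]; }
  c[0] = u[1] * v[2] - u[2] * v[1];
  c[1] = u[2] * v[0] - u[0] * v[2];
  c[2] = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(c[0] * c[0] + c[1] * c[1] + c[2] * c[2]);
}

// Surface area of the iso-surface {field == iso} by marching tetrahedra
// (each grid cube split into 6 tetrahedra sharing the main diagonal), with
// vertices at voxel centres in physical coordinates. Returns area in um^2.
// [[Rcpp::export]]
double cpp_isosurface_area(NumericVector field, IntegerVector dims,
                           NumericVector spacing, double iso) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  double dzs = spacing[0], dys = spacing[1], dxs = spacing[2];
  // cube corner offsets (z,y,x) for vertices v0..v7, diagonal v0-v6
  static const int off[8][3] = {
    {0,0,0},{0,0,1},{0,1,1},{0,1,0},{1,0,0},{1,0,1},{1,1,1},{1,1,0}};
  static const int tets[6][4] = {
    {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}};
  double area = 0;
  double P[8][3]; double F[8];
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        bool anyAbove = false, anyBelow = false;
        for (int c = 0; c < 8; ++c) {
          int zz = z + off[c][0], yy = y + off[c][1], xx = x + off[c][2];
          F[c] = field[idx3(zz, yy, xx, nz, ny)];
          P[c][0] = zz * dzs; P[c][1] = yy * dys; P[c][2] = xx * dxs;
          if (F[c] > iso) anyAbove = true; else anyBelow = true;
        }
        if (!anyAbove || !anyBelow) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int above[4], below[4];
          int na = 0, nb = 0;
          for (int c = 0; c < 4; ++c) {
            if (F[vi[c]] > iso) above[na++] = vi[c];
            else below[nb++] = vi[c];
          }
          if (na == 0 || na == 4) continue;
          double e[4][3];
          if (na == 1 || na == 3) {
            int apex = (na == 1) ? above[0] : below[0];
            int *base = (na == 1) ? below : above;
            for (int c = 0; c < 3; ++c)
              lerp3(P[apex], P[base[c]], F[apex], F[base[c]], iso, e[c]);
            area += triarea(e[0], e[1], e[2]);
          } else {  // 2-2: quad = (a0c0, a0c1, a1c1, a1c0)
            lerp3(P[above[0]], P[below[0]], F[above[0]], F[below[0]], iso, e[0]);
            lerp3(P[above[0]], P[below[1]], F[above[0]], F[below[1]], iso, e[1]);
            lerp3(P[above[1]], P[below[1]], F[above[1]], F[below[1]], iso, e[2]);
            lerp3(P[above[1]], P[below[0]], F[above[1]], F[below[0]], iso, e[3]);
            area += triarea(e[0], e[1], e[2]) + triarea(e[0], e[2], e[3]);
          }
        }
      }
  return area;
}

// ---------------------------------------------------- convex hull volume ---

struct Face { int a, b, c; double nx, ny, nz, d; bool alive; };

static void face_plane(const std::vector<double> &px,
                       const std::vector<double> &py,
                       const std::vector<double> &pz, Face &f) {
  double ux = px[f.b] - px[f.a], uy = py[f.b] - py[f.a], uz = pz[f.b] - pz[f.a];
  double vx = px[f.c] - px[f.a], vy = py[f.c] - py[f.a], vz = pz[f.c] - pz[f.a];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.d = f.nx * px[f.a] + f.ny * py[f.a] + f.nz * pz[f.a];
}

// Incremental convex hull with a tiny deterministic perturbation to break
// grid degeneracies. Fills `faces` (alive entries only are valid) and the
// interior reference point (ox, oy, oz). Returns false for degenerate input.
static bool build_hull(std::vector<double> &px, std::vector<double> &py,
                       std::vector<double> &pz, std::vector<Face> &faces,
                       double &ox, double &oy, double &oz) {
  int n = (int)px.size();
  if (n < 4) return false;
  double xmin = R_PosInf, xmax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, std::min(px[i], std::min(py[i], pz[i])));
    xmax = std::max(xmax, std::max(px[i], std::max(py[i], pz[i])));
  }
  double scale = std::max(1e-12, xmax - xmin);
  double eps = 1e-4 * scale;
  // deterministic jitter (decorrelated hash of index) to avoid coplanarity
  for (int i = 0; i < n; ++i) {
    double h1 = std::sin((i + 1) * 12.9898) * 43758.5453;
    double h2 = std::sin((i + 1) * 78.2330) * 24634.6345;
    double h3 = std::sin((i + 1) * 37.7190) * 36563.5353;
    px[i] += eps * (h1 - std::floor(h1) - 0.5);
    py[i] += eps * (h2 - std::floor(h2) - 0.5);
    pz[i] += eps * (h3 - std::floor(h3) - 0.5);
  }
  // initial tetrahedron from extreme points
  int i0 = 0, i1 = 0;
  for (int i = 0; i < n; ++i) {
    if (px[i] < px[i0]) i0 = i;
    if (px[i] > px[i1]) i1 = i;
  }
  if (i0 == i1) return false;
  int i2 = -1; double best = -1;
  for (int i = 0; i < n; ++i) {
    double ax = px[i1] - px[i0], ay = py[i1] - py[i0], az = pz[i1] - pz[i0];
    double bx = px[i] - px[i0], by = py[i] - py[i0], bz = pz[i] - pz[i0];
    double cx = ay * bz - az * by, cy = az * bx - ax * bz, cz = ax * by - ay * bx;
    double a2 = cx * cx + cy * cy + cz * cz;
    if (a2 > best) { best = a2; i2 = i; }
  }
  int i3 = -1; best = -1;
  {
    Face f{i0, i1, i2, 0, 0, 0, 0, true};
    face_plane(px, py, pz, f);
    for (int i = 0; i < n; ++i) {
      double v = std::fabs(f.nx * px[i] + f.ny * py[i] + f.nz * pz[i] - f.d);
      if (v > best) { best = v; i3 = i; }
    }
  }
  if (i3 < 0) return false;
  ox = (px[i0] + px[i1] + px[i2] + px[i3]) / 4.0;
  oy = (py[i0] + py[i1] + py[i2] + py[i3]) / 4.0;
  oz = (pz[i0] + pz[i1] + pz[i2] + pz[i3]) / 4.0;
  faces.clear();
  auto add_face = [&](int a, int b, int c) {
    Face f{a, b, c, 0, 0, 0, 0, true};
    face_plane(px, py, pz, f);
    // orient outward w.r.t. interior point o
    if (f.nx * ox + f.ny * oy + f.nz * oz - f.d > 0) {
      std::swap(f.b, f.c);
      face_plane(px, py, pz, f);
    }
    faces.push_back(f);
  };
  add_face(i0, i1, i2); add_face(i0, i1, i3);
  add_face(i0, i2, i3); add_face(i1, i2, i3);
  double tol = 1e-6 * scale;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double nrm = std::sqrt(faces[f].nx * faces[f].nx +
                             faces[f].ny * faces[f].ny +
                             faces[f].nz * faces[f].nz);
      double s = (faces[f].nx * px[i] + faces[f].ny * py[i] +
                  faces[f].nz * pz[i] - faces[f].d) / std::max(nrm, 1e-300);
      if (s > tol) vis.push_back(f);
    }
    if (vis.empty()) continue;
    // horizon: edges appearing exactly once among visible faces
    std::vector<std::pair<int, int> > edges;
    for (int f : vis) {
      int vv[3] = {faces[f].a, faces[f].b, faces[f].c};
      for (int e = 0; e < 3; ++e) {
        int a = vv[e], b = vv[(e + 1) % 3];
        int lo = std::min(a, b), hi = std::max(a, b);
        bool found = false;
        for (size_t k = 0; k < edges.size(); ++k)
          if (edges[k].first == lo && edges[k].second == hi) {
            edges.erase(edges.begin() + k);
            found = true;
            break;
          }
        if (!found) edges.push_back({lo, hi});
      }
    }
    for (int f : vis) faces[f].alive = false;
    for (auto &e : edges) add_face(e.first, e.second, i);
  }
  return true;
}

// Volume of the convex hull of a 3D point cloud (n x 3 matrix of physical
// coordinates). Returns volume in um^3; 0 for degenerate input.
// [[Rcpp::export]]
double cpp_hull_volume(NumericMatrix pts) {
  int n = pts.nrow();
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
  }
  std::vector<Face> faces;
  double ox, oy, oz;
  if (!build_hull(px, py, pz, faces, ox, oy, oz)) return 0.0;
  double vol = 0;
  for (auto &f : faces) {
    if (!f.alive) continue;
    double ax = px[f.a] - ox, ay = py[f.a] - oy, az = pz[f.a] - oz;
    double bx = px[f.b] - ox, by = py[f.b] - oy, bz = pz[f.b] - oz;
    double cx = px[f.c] - ox, cy = py[f.c] - oy, cz = pz[f.c] - oz;
    double det = ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
                 az * (bx * cy - by * cx);
    vol += std::fabs(det) / 6.0;
  }
  return vol;
}

// Number of integer lattice points (z, y, x) inside the convex hull of the
// given integer points (n x 3 matrix). The hull is rasterized line by line:
// for every (z, y) in the bounding box the half-space constraints yield an
// x-interval, whose integer points are counted. Used for solidity.
// [[Rcpp::export]]
double cpp_hull_raster_count(NumericMatrix pts) {
  int n = pts.nrow();
  std::vector<double> pz(n), py(n), px(n);
  double zmin = R_PosInf, zmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    pz[i] = pts(i, 0); py[i] = pts(i, 1); px[i] = pts(i, 2);
    zmin = std::min(zmin, pz[i]); zmax = std::max(zmax, pz[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  std::vector<Face> faces;
  double ox, oy, oz;
  // build_hull works on (x, y, z) triplets; axis naming is immaterial
  if (!build_hull(pz, py, px, faces, ox, oy, oz)) return (double)n;
  std::vector<Face> live;
  for (auto &f : faces)
    if (f.alive) {
      Face g = f;
      // offset the plane outward by delta so lattice points lying exactly on
      // the true hull boundary (within the jitter) stay inside
      double nrm = std::sqrt(g.nx * g.nx + g.ny * g.ny + g.nz * g.nz);
      g.d += 1e-2 * nrm;
      live.push_back(g);
    }
  double count = 0;
  for (int z = (int)std::floor(zmin); z <= (int)std::ceil(zmax); ++z)
    for (int y = (int)std::floor(ymin); y <= (int)std::ceil(ymax); ++y) {
      double tlo = -1e30, thi = 1e30;
      bool empty = false;
      for (auto &f : live) {
        // outward normal: f.nx * z + f.ny * y + f.nz * t <= f.d
        double rem = f.d - f.nx * z - f.ny * y;
        if (std::fabs(f.nz) < 1e-12) {
          if (rem < 0) { empty = true; break; }
        } else if (f.nz > 0) {
          thi = std::min(thi, rem / f.nz);
        } else {
          tlo = std::max(tlo, rem / f.nz);
        }
      }
      if (empty || thi < tlo) continue;
      double lo = std::ceil(tlo - 1e-9), hi = std::floor(thi + 1e-9);
      if (hi >= lo) count += hi - lo + 1;
    }
  return count;
}
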