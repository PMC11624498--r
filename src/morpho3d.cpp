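// 3D binary-morphology primitives used by the segmentation and skeleton
// stages: exact Euclidean distance transform (separable lower-envelope
// algorithm), connected-component labelling (26-connectivity), and curve
// skeletonization by sequential deletion of (26,6) simple points ordered by
// distance-to-boundary.
//
// Volumes are R arrays in column-major order with dim = (nz, ny, nx);
// axis 1 is depth z. Linear index: z + nz*(y + ny*x).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
// large finite stand-in for "no background seen yet"; keeps the parabola
// intersection arithmetic finite on all-foreground rows
static const double BIG = 1e20;

// 1D squared-distance transform on a sampled grid with spacing s
// (Felzenszwalb & Huttenlocher lower envelope of parabolas).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double xv = v[k] * s;
    double sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
    while (sint <= z[k]) {
      --k;
      xv = v[k] * s;
      sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Squared Euclidean distance from each foreground voxel to the nearest
// background voxel (background gets 0). spacing = (dz, dy, dx) in um.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax);

  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; ++z) f[z] = out[base + z];
      dt1d(f, d, nz, spacing[0]);
      for (int z = 0; z < nz; ++z) out[base + z] = d[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y)
        f[y] = out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y)
        out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = d[y];
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x)
        f[x] = out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
      dt1d(f, d, nx, spacing[2]);
      for (int x = 0; x < nx; ++x)
        out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = d[x];
    }
  return out;
}

// ---- neighbourhood machinery for the simple-point test --------------------

// offsets of the 3x3x3 neighbourhood minus the centre, fixed order
static int NB[26][3];
static bool nb_ready = false;
static void init_nb() {
  if (nb_ready) return;
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        NB[k][0] = dz; NB[k][1] = dy; NB[k][2] = dx;
        ++k;
      }
  nb_ready = true;
}

static inline bool in_vol(int z, int y, int x, int nz, int ny, int nx) {
  return z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx;
}

// A foreground voxel is (26,6)-simple iff (a) its foreground 26-neighbours
// form exactly one 26-connected component, and (b) the background voxels of
// its 18-neighbourhood that are 6-adjacent (directly or through the
// 18-neighbourhood) to a face-neighbour form exactly one 6-connected
// component (topological characterization of simple points).
static bool is_simple(const std::vector<unsigned char>& img,
                      int z, int y, int x, int nz, int ny, int nx) {
  bool fg[26];
  int nfg = 0;
  for (int k = 0; k < 26; ++k) {
    int zz = z + NB[k][0], yy = y + NB[k][1], xx = x + NB[k][2];
    fg[k] = in_vol(zz, yy, xx, nz, ny, nx) &&
            img[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
    if (fg[k]) ++nfg;
  }
  if (nfg == 0) return false;

  // (a) one 26-component among foreground neighbours
  int comp = 0;
  bool seen[26] = {false};
  for (int s = 0; s < 26; ++s) {
    if (!fg[s] || seen[s]) continue;
    if (++comp > 1) return false;
    std::queue<int> q;
    q.push(s); seen[s] = true;
    while (!q.empty()) {
      int a = q.front(); q.pop();
      for (int b = 0; b < 26; ++b) {
        if (!fg[b] || seen[b]) continue;
        if (std::abs(NB[a][0] - NB[b][0]) <= 1 &&
            std::abs(NB[a][1] - NB[b][1]) <= 1 &&
            std::abs(NB[a][2] - NB[b][2]) <= 1) {
          seen[b] = true; q.push(b);
        }
      }
    }
  }
  if (comp != 1) return false;

  // (b) background 6-components within the 18-neighbourhood touching a
  // face-neighbour
  bool bg18[26];
  for (int k = 0; k < 26; ++k) {
    int l1 = std::abs(NB[k][0]) + std::abs(NB[k][1]) + std::abs(NB[k][2]);
    bg18[k] = (l1 <= 2) && !fg[k];
  }
  comp = 0;
  bool seen2[26] = {false};
  for (int s = 0; s < 26; ++s) {
    int l1 = std::abs(NB[s][0]) + std::abs(NB[s][1]) + std::abs(NB[s][2]);
    if (l1 != 1 || !bg18[s] || seen2[s]) continue; // seed at face-neighbours
    if (++comp > 1) return false;
    std::queue<int> q;
    q.push(s); seen2[s] = true;
    while (!q.empty()) {
      int a = q.front(); q.pop();
      for (int b = 0; b < 26; ++b) {
        if (!bg18[b] || seen2[b]) continue;
        if (std::abs(NB[a][0] - NB[b][0]) +
            std::abs(NB[a][1] - NB[b][1]) +
            std::abs(NB[a][2] - NB[b][2]) == 1) {
          seen2[b] = true; q.push(b);
        }
      }
    }
  }
  return comp == 1;
}

static inline int count_fg_neighbours(const std::vector<unsigned char>& img,
                                      int z, int y, int x,
                                      int nz, int ny, int nx) {
  int c = 0;
  for (int k = 0; k < 26; ++k) {
    int zz = z + NB[k][0], yy = y + NB[k][1], xx = x + NB[k][2];
    if (in_vol(zz, yy, xx, nz, ny, nx) &&
        img[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)])
      ++c;
  }
  return c;
}

static inline bool has_bg_face_neighbour(const std::vector<unsigned char>& img,
                                         int z, int y, int x,
                                         int nz, int ny, int nx) {
  static const int F[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  for (int k = 0; k < 6; ++k) {
    int zz = z + F[k][0], yy = y + F[k][1], xx = x + F[k][2];
    if (!in_vol(zz, yy, xx, nz, ny, nx) ||
        !img[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)])
      return true;
  }
  return false;
}

// Thin a binary volume to a 26-connected curve skeleton by directional
// subiterations: cycling through the six face directions, border voxels
// whose face-neighbour in the current direction is background — and that
// are simple and not curve endpoints (<=1 foreground neighbour) — are
// deleted sequentially, smallest distance-to-boundary first (lexicographic
// voxel order breaks ties), until a full cycle makes no deletion.
// Sequential rechecking keeps every deletion topology-safe; the directional
// schedule removes at most one layer per direction per cycle (preventing
// runaway longitudinal erosion of thick cores) and, with the distance
// ordering, centres the skeleton.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  init_nb();
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<unsigned char> img(n);
  for (R_xlen_t i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;

  NumericVector edt = cpp_edt3d(mask, dim, spacing);

  static const int DIR[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  struct Cand { double d; R_xlen_t idx; };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      std::vector<Cand> cands;
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
            if (!img[i]) continue;
            int zz = z + DIR[dir][0], yy = y + DIR[dir][1], xx = x + DIR[dir][2];
            bool bg = !in_vol(zz, yy, xx, nz, ny, nx) ||
              !img[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
            if (!bg) continue;
            int cfg = count_fg_neighbours(img, z, y, x, nz, ny, nx);
            if (cfg <= 1) continue; // endpoint or isolated: keep
            if (!is_simple(img, z, y, x, nz, ny, nx)) continue;
            cands.push_back({edt[i], i});
          }
      std::sort(cands.begin(), cands.end(),
                [](const Cand& a, const Cand& b) {
                  return a.d != b.d ? a.d < b.d : a.idx < b.idx;
                });
      for (const Cand& c : cands) {
        R_xlen_t i = c.idx;
        int x = (int)(i / ((R_xlen_t)nz * ny));
        int rem = (int)(i - (R_xlen_t)nz * ny * x);
        int y = rem / nz, z = rem % nz;
        if (count_fg_neighbours(img, z, y, x, nz, ny, nx) <= 1) continue;
        if (!is_simple(img, z, y, x, nz, ny, nx)) continue;
        img[i] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = img[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// Label 26-connected foreground components; labels start at 1 in
// lexicographic (z fastest) order of each component's first voxel.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  init_nb();
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      R_xlen_t j = stack.back(); stack.pop_back();
      int x = (int)(j / ((R_xlen_t)nz * ny));
      int rem = (int)(j - (R_xlen_t)nz * ny * x);
      int y = rem / nz, z = rem % nz;
      for (int k = 0; k < 26; ++k) {
        int zz = z + NB[k][0], yy = y + NB[k][1], xx = x + NB[k][2];
        if (!in_vol(zz, yy, xx, nz, ny, nx)) continue;
        R_xlen_t jj = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[jj] && !lab[jj]) {
          lab[jj] = next;
          stack.push_back(jj);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Number of foreground 26-neighbours for every voxel of a binary volume
// (used to classify skeleton voxels into endpoints/slabs/junctions).
// [[Rcpp::export]]
IntegerVector cpp_neighbour_count(LogicalVector mask, IntegerVector dim) {
  init_nb();
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<unsigned char> img(n);
  for (R_xlen_t i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;
  IntegerVector out(n);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        out[i] = img[i] ? count_fg_neighbours(img, z, y, x, nz, ny, nx) : 0;
      }
  out.attr("dim") = dim;
  return out;
}
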