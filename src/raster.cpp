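// Tube rasterization as a chain of capsules: a voxel is foreground when its
// centre lies within the (linearly interpolated) radius of a centerline
// segment. Voxel i (1-based) spans [(i-1)*s, i*s] um with centre at
// (i-0.5)*s.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// segs: n x 10 matrix (z1, y1, x1, r1, z2, y2, x2, r2, cap1, cap2) in um;
// cap1/cap2 nonzero allow the capsule to extend past that endpoint as a
// hemispherical cap (used at interior joints of a polyline so consecutive
// cylinders stay connected at bends); terminal branch ends stay flat so a
// straight tube has the analytic cylinder volume.
// dim = (nz, ny, nx); spacing = (dz, dy, dx) um. Marks voxels in `vox`.
// [[Rcpp::export]]
LogicalVector cpp_stamp_tubes(NumericMatrix segs, IntegerVector dim,
                              NumericVector spacing, LogicalVector vox) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  for (int s = 0; s < segs.nrow(); ++s) {
    const double az = segs(s, 0), ay = segs(s, 1), ax = segs(s, 2),
                 r1 = segs(s, 3);
    const double bz = segs(s, 4), by = segs(s, 5), bx = segs(s, 6),
                 r2 = segs(s, 7);
    const bool cap1 = segs(s, 8) != 0.0, cap2 = segs(s, 9) != 0.0;
    const double rmax = std::max(r1, r2);
    const double lo_z = std::min(az, bz) - rmax, hi_z = std::max(az, bz) + rmax;
    const double lo_y = std::min(ay, by) - rmax, hi_y = std::max(ay, by) + rmax;
    const double lo_x = std::min(ax, bx) - rmax, hi_x = std::max(ax, bx) + rmax;
    int z0 = std::max(0, (int)std::floor(lo_z / dz));
    int z1i = std::min(nz - 1, (int)std::ceil(hi_z / dz));
    int y0 = std::max(0, (int)std::floor(lo_y / dy));
    int y1i = std::min(ny - 1, (int)std::ceil(hi_y / dy));
    int x0 = std::max(0, (int)std::floor(lo_x / dx));
    int x1i = std::min(nx - 1, (int)std::ceil(hi_x / dx));
    const double vz = bz - az, vy = by - ay, vx = bx - ax;
    const double L2 = vz * vz + vy * vy + vx * vx;
    for (int x = x0; x <= x1i; ++x) {
      const double px = (x + 0.5) * dx;
      for (int y = y0; y <= y1i; ++y) {
        const double py = (y + 0.5) * dy;
        for (int z = z0; z <= z1i; ++z) {
          R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
          if (vox[i]) continue;
          const double pz = (z + 0.5) * dz;
          double t = 0.0;
          if (L2 > 0.0) {
            t = ((pz - az) * vz + (py - ay) * vy + (px - ax) * vx) / L2;
            if ((t < 0.0 && !cap1) || (t > 1.0 && !cap2)) continue;
            t = std::min(1.0, std::max(0.0, t));
          }
          const double qz = az + t * vz, qy = ay + t * vy, qx = ax + t * vx;
          const double r = r1 + t * (r2 - r1);
          const double d2 = (pz - qz) * (pz - qz) + (py - qy) * (py - qy) +
            (px - qx) * (px - qx);
          if (d2 <= r * r) vox[i] = true;
        }
      }
    }
  }
  return vox;
}
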