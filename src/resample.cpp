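#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rigid resampling of a 3-D volume: out(x) = in(Rinv (x - c - t) + c),
// with trilinear or cubic (Keys, a = -0.5) interpolation, zero outside.
// Rinv is passed as a 9-vector (column-major 3x3), c is the grid centre in
// 1-based voxel coordinates, t the translation in voxels.

namespace {
inline double keys3(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}
}

// [[Rcpp::export]]
NumericVector resample_rigid_cpp(NumericVector vol, IntegerVector dim,
                                 NumericVector rinv, NumericVector center,
                                 NumericVector translation, bool cubic) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  const double cx = center[0], cy = center[1], cz = center[2];
  const double tx = translation[0], ty = translation[1], tz = translation[2];

  auto at = [&](int x, int y, int z) -> double {
    if (x < 1 || x > nx || y < 1 || y > ny || z < 1 || z > nz) return 0.0;
    return vol[(size_t)(z - 1) * nx * ny + (size_t)(y - 1) * nx + (x - 1)];
  };

  size_t o = 0;
  for (int z = 1; z <= nz; ++z) {
    for (int y = 1; y <= ny; ++y) {
      for (int x = 1; x <= nx; ++x, ++o) {
        const double dx = x - cx - tx, dy = y - cy - ty, dz = z - cz - tz;
        const double sx = rinv[0] * dx + rinv[3] * dy + rinv[6] * dz + cx;
        const double sy = rinv[1] * dx + rinv[4] * dy + rinv[7] * dz + cy;
        const double sz = rinv[2] * dx + rinv[5] * dy + rinv[8] * dz + cz;
        double acc = 0.0;
        if (cubic) {
          const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
                    z0 = (int)std::floor(sz);
          for (int kz = -1; kz <= 2; ++kz) {
            const double wz = keys3(sz - (z0 + kz));
            if (wz == 0.0) continue;
            for (int ky = -1; ky <= 2; ++ky) {
              const double wy = keys3(sy - (y0 + ky));
              if (wy == 0.0) continue;
              for (int kx = -1; kx <= 2; ++kx) {
                const double wx = keys3(sx - (x0 + kx));
                if (wx == 0.0) continue;
                acc += wx * wy * wz * at(x0 + kx, y0 + ky, z0 + kz);
              }
            }
          }
        } else {
          const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
                    z0 = (int)std::floor(sz);
          const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
          for (int kz = 0; kz <= 1; ++kz)
            for (int ky = 0; ky <= 1; ++ky)
              for (int kx = 0; kx <= 1; ++kx) {
                const double w = (kx ? fx : 1 - fx) * (ky ? fy : 1 - fy) *
                                 (kz ? fz : 1 - fz);
                acc += w * at(x0 + kx, y0 + ky, z0 + kz);
              }
        }
        out[o] = acc;
      }
    }
  }
  return out;
}
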