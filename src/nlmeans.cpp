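#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rician-aware non-local means for one 3-D volume.
// Patch distance is the mean squared difference between patches; the
// expected distance between two identical noisy patches (2 sigma^2) is
// subtracted before the Gaussian weight. Averaging runs over squared
// magnitudes and the Rician bias 2 sigma^2 is removed at the end.
// [[Rcpp::export]]
NumericVector nlmeans_rician_cpp(NumericVector vol, IntegerVector dim,
                                 double sigma, int patch_radius,
                                 int search_radius, double h) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double twos2 = 2.0 * sigma * sigma;
  const double h2 = std::max(h * h, 1e-300);
  NumericVector out(vol.size());

  auto at = [&](int x, int y, int z) -> double {
    // clamped access
    x = std::min(std::max(x, 0), nx - 1);
    y = std::min(std::max(y, 0), ny - 1);
    z = std::min(std::max(z, 0), nz - 1);
    return vol[(size_t)z * nx * ny + (size_t)y * nx + x];
  };

  const int pr = patch_radius, sr = search_radius;
  const double npatch = std::pow(2.0 * pr + 1.0, 3);

  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        double wsum = 0.0, acc = 0.0;
        for (int dz = -sr; dz <= sr; ++dz) {
          for (int dy = -sr; dy <= sr; ++dy) {
            for (int dx = -sr; dx <= sr; ++dx) {
              const int qx = x + dx, qy = y + dy, qz = z + dz;
              if (qx < 0 || qx >= nx || qy < 0 || qy >= ny ||
                  qz < 0 || qz >= nz) continue;
              double msd = 0.0;
              for (int pz = -pr; pz <= pr; ++pz)
                for (int py = -pr; py <= pr; ++py)
                  for (int px = -pr; px <= pr; ++px) {
                    const double d = at(x + px, y + py, z + pz) -
                                     at(qx + px, qy + py, qz + pz);
                    msd += d * d;
                  }
              msd /= npatch;
              const double w = std::exp(-std::max(msd - twos2, 0.0) / h2);
              const double q = at(qx, qy, qz);
              wsum += w;
              acc += w * q * q;
            }
          }
        }
        const double nl2 = acc / wsum;
        out[(size_t)z * nx * ny + (size_t)y * nx + x] =
            std::sqrt(std::max(nl2 - twos2, 0.0));
      }
    }
  }
  return out;
}
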