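#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic Euler streamline integration over a principal-eigenvector
// field, with FA, turning-angle and length gates. Interpolation is either
// trilinear or cubic (Keys / Catmull-Rom convolution, which interpolates
// exactly at voxel centres); eigenvector neighbours are sign-aligned with
// the incoming direction before blending, so antipodal storage never
// averages to a shortened vector.

namespace {

struct Field {
  const double *fa;       // nx*ny*nz
  const double *e1;       // nx*ny*nz*3
  int nx, ny, nz;
  double vx, vy, vz;      // voxel size mm

  size_t nvox() const { return (size_t)nx * ny * nz; }

  double fa_at(int x, int y, int z) const {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0.0;
    return fa[(size_t)z * nx * ny + (size_t)y * nx + x];
  }
  void e1_at(int x, int y, int z, double out[3]) const {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) {
      out[0] = out[1] = out[2] = 0.0;
      return;
    }
    const size_t i = (size_t)z * nx * ny + (size_t)y * nx + x;
    out[0] = e1[i];
    out[1] = e1[i + nvox()];
    out[2] = e1[i + 2 * nvox()];
  }
};

// Keys cubic convolution kernel, a = -0.5 (Catmull-Rom)
inline double keys(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

// voxel-continuous coordinates: voxel centre i is at coordinate i (0-based)
inline void mm_to_vox(const Field &f, const double p[3], double v[3]) {
  v[0] = p[0] / f.vx - 0.5;
  v[1] = p[1] / f.vy - 0.5;
  v[2] = p[2] / f.vz - 0.5;
}

double interp_fa(const Field &f, const double pmm[3], bool cubic) {
  double v[3];
  mm_to_vox(f, pmm, v);
  if (cubic) {
    const int x0 = (int)std::floor(v[0]), y0 = (int)std::floor(v[1]),
              z0 = (int)std::floor(v[2]);
    double acc = 0.0;
    for (int dz = -1; dz <= 2; ++dz) {
      const double wz = keys(v[2] - (z0 + dz));
      if (wz == 0.0) continue;
      for (int dy = -1; dy <= 2; ++dy) {
        const double wy = keys(v[1] - (y0 + dy));
        if (wy == 0.0) continue;
        for (int dx = -1; dx <= 2; ++dx) {
          const double wx = keys(v[0] - (x0 + dx));
          if (wx == 0.0) continue;
          acc += wx * wy * wz * f.fa_at(x0 + dx, y0 + dy, z0 + dz);
        }
      }
    }
    return acc;
  }
  const int x0 = (int)std::floor(v[0]), y0 = (int)std::floor(v[1]),
            z0 = (int)std::floor(v[2]);
  const double fx = v[0] - x0, fy = v[1] - y0, fz = v[2] - z0;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                         (dz ? fz : 1 - fz);
        acc += w * f.fa_at(x0 + dx, y0 + dy, z0 + dz);
      }
  return acc;
}

// returns false if the interpolated direction is degenerate
bool interp_dir(const Field &f, const double pmm[3], const double ref[3],
                bool cubic, double out[3]) {
  double v[3];
  mm_to_vox(f, pmm, v);
  const int lo = cubic ? -1 : 0, hi = cubic ? 2 : 1;
  const int x0 = (int)std::floor(v[0]), y0 = (int)std::floor(v[1]),
            z0 = (int)std::floor(v[2]);
  double acc[3] = {0, 0, 0};
  for (int dz = lo; dz <= hi; ++dz) {
    const double wz = cubic ? keys(v[2] - (z0 + dz))
                            : (dz ? v[2] - z0 : 1 - (v[2] - z0));
    if (wz == 0.0) continue;
    for (int dy = lo; dy <= hi; ++dy) {
      const double wy = cubic ? keys(v[1] - (y0 + dy))
                              : (dy ? v[1] - y0 : 1 - (v[1] - y0));
      if (wy == 0.0) continue;
      for (int dx = lo; dx <= hi; ++dx) {
        const double wx = cubic ? keys(v[0] - (x0 + dx))
                                : (dx ? v[0] - x0 : 1 - (v[0] - x0));
        if (wx == 0.0) continue;
        double e[3];
        f.e1_at(x0 + dx, y0 + dy, z0 + dz, e);
        // sign-align with the incoming direction before blending
        const double dot = e[0] * ref[0] + e[1] * ref[1] + e[2] * ref[2];
        const double s = (dot < 0.0) ? -1.0 : 1.0;
        const double w = wx * wy * wz;
        acc[0] += w * s * e[0];
        acc[1] += w * s * e[1];
        acc[2] += w * s * e[2];
      }
    }
  }
  const double nrm = std::sqrt(acc[0] * acc[0] + acc[1] * acc[1] +
                               acc[2] * acc[2]);
  if (nrm < 1e-8) return false;
  out[0] = acc[0] / nrm;
  out[1] = acc[1] / nrm;
  out[2] = acc[2] / nrm;
  return true;
}

// trace one direction from a seed; returns points (excluding the seed)
std::vector<double> trace_half(const Field &f, const double seed[3],
                               const double dir0[3], double step,
                               double fa_thr, double cos_thr, bool cubic,
                               int max_steps) {
  std::vector<double> pts;
  double p[3] = {seed[0], seed[1], seed[2]};
  double d[3] = {dir0[0], dir0[1], dir0[2]};
  for (int i = 0; i < max_steps; ++i) {
    double q[3] = {p[0] + step * d[0], p[1] + step * d[1],
                   p[2] + step * d[2]};
    double v[3];
    mm_to_vox(f, q, v);
    if (v[0] < 0 || v[0] > f.nx - 1 || v[1] < 0 || v[1] > f.ny - 1 ||
        v[2] < 0 || v[2] > f.nz - 1)
      break; // left the grid
    if (interp_fa(f, q, cubic) < fa_thr) break;
    double nd[3];
    if (!interp_dir(f, q, d, cubic, nd)) break;
    const double ca = nd[0] * d[0] + nd[1] * d[1] + nd[2] * d[2];
    if (ca < cos_thr) break; // turning angle exceeded
    pts.push_back(q[0]); pts.push_back(q[1]); pts.push_back(q[2]);
    p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
    d[0] = nd[0]; d[1] = nd[1]; d[2] = nd[2];
  }
  return pts;
}

} // namespace

// [[Rcpp::export]]
List track_cpp(NumericVector fa, NumericVector e1, IntegerVector dim,
               NumericVector voxel_mm, NumericMatrix seeds_mm,
               double fa_threshold, double angle_threshold_deg,
               double step_mm, double min_len_mm, double max_len_mm,
               int n_target, bool cubic) {
  Field f;
  f.fa = fa.begin();
  f.e1 = e1.begin();
  f.nx = dim[0]; f.ny = dim[1]; f.nz = dim[2];
  f.vx = voxel_mm[0]; f.vy = voxel_mm[1]; f.vz = voxel_mm[2];

  const double cos_thr = std::cos(angle_threshold_deg * M_PI / 180.0);
  const int max_steps = (int)std::ceil(max_len_mm / step_mm) + 2;

  List kept;
  std::vector<int> seed_used;
  for (int s = 0; s < seeds_mm.nrow(); ++s) {
    if ((int)kept.size() >= n_target) break;
    double seed[3] = {seeds_mm(s, 0), seeds_mm(s, 1), seeds_mm(s, 2)};
    if (interp_fa(f, seed, cubic) < fa_threshold) continue;
    double d0[3];
    double any[3] = {1, 0, 0};
    if (!interp_dir(f, seed, any, cubic, d0)) continue;
    std::vector<double> fwd = trace_half(f, seed, d0, step_mm, fa_threshold,
                                         cos_thr, cubic, max_steps);
    double d0n[3] = {-d0[0], -d0[1], -d0[2]};
    std::vector<double> bwd = trace_half(f, seed, d0n, step_mm, fa_threshold,
                                         cos_thr, cubic, max_steps);
    const int nf = fwd.size() / 3, nb = bwd.size() / 3;
    const int npts = nf + nb + 1;
    const double len = (npts - 1) * step_mm;
    if (len < min_len_mm || len > max_len_mm) continue;
    NumericMatrix line(npts, 3);
    // backward half reversed, then the seed, then the forward half
    for (int i = 0; i < nb; ++i) {
      const int j = nb - 1 - i;
      line(i, 0) = bwd[3 * j]; line(i, 1) = bwd[3 * j + 1];
      line(i, 2) = bwd[3 * j + 2];
    }
    line(nb, 0) = seed[0]; line(nb, 1) = seed[1]; line(nb, 2) = seed[2];
    for (int i = 0; i < nf; ++i) {
      line(nb + 1 + i, 0) = fwd[3 * i]; line(nb + 1 + i, 1) = fwd[3 * i + 1];
      line(nb + 1 + i, 2) = fwd[3 * i + 2];
    }
    kept.push_back(line);
    seed_used.push_back(s + 1);
  }
  return List::create(_["streamlines"] = kept,
                      _["seed_index"] = wrap(seed_used));
}

// [[Rcpp::export]]
NumericVector interp_dir_cpp(NumericVector e1, IntegerVector dim,
                             NumericVector voxel_mm, NumericVector point_mm,
                             NumericVector ref_dir, bool cubic,
                             bool renormalize) {
  Field f;
  f.fa = nullptr;
  f.e1 = e1.begin();
  f.nx = dim[0]; f.ny = dim[1]; f.nz = dim[2];
  f.vx = voxel_mm[0]; f.vy = voxel_mm[1]; f.vz = voxel_mm[2];
  double v[3];
  const double p[3] = {point_mm[0], point_mm[1], point_mm[2]};
  mm_to_vox(f, p, v);
  if (v[0] < 0 || v[0] > f.nx - 1 || v[1] < 0 || v[1] > f.ny - 1 ||
      v[2] < 0 || v[2] > f.nz - 1)
    return NumericVector::create(NA_REAL, NA_REAL, NA_REAL);
  const double ref[3] = {ref_dir[0], ref_dir[1], ref_dir[2]};
  // unnormalised blend, so callers can check the pre-normalisation norm
  const int lo = cubic ? -1 : 0, hi = cubic ? 2 : 1;
  const int x0 = (int)std::floor(v[0]), y0 = (int)std::floor(v[1]),
            z0 = (int)std::floor(v[2]);
  double acc[3] = {0, 0, 0};
  for (int dz = lo; dz <= hi; ++dz) {
    const double wz = cubic ? keys(v[2] - (z0 + dz))
                            : (dz ? v[2] - z0 : 1 - (v[2] - z0));
    for (int dy = lo; dy <= hi; ++dy) {
      const double wy = cubic ? keys(v[1] - (y0 + dy))
                              : (dy ? v[1] - y0 : 1 - (v[1] - y0));
      for (int dx = lo; dx <= hi; ++dx) {
        const double wx = cubic ? keys(v[0] - (x0 + dx))
                                : (dx ? v[0] - x0 : 1 - (v[0] - x0));
        double e[3];
        f.e1_at(x0 + dx, y0 + dy, z0 + dz, e);
        const double dot = e[0] * ref[0] + e[1] * ref[1] + e[2] * ref[2];
        const double sg = (dot < 0.0) ? -1.0 : 1.0;
        const double w = wx * wy * wz;
        acc[0] += w * sg * e[0];
        acc[1] += w * sg * e[1];
        acc[2] += w * sg * e[2];
      }
    }
  }
  if (renormalize) {
    const double nrm = std::sqrt(acc[0] * acc[0] + acc[1] * acc[1] +
                                 acc[2] * acc[2]);
    if (nrm > 1e-12) {
      acc[0] /= nrm; acc[1] /= nrm; acc[2] /= nrm;
    }
  }
  return NumericVector::create(acc[0], acc[1], acc[2]);
}
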