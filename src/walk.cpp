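// Continuous-space Monte-Carlo random walk inside a labeled voxel substrate.
//
// Geometry conventions (match the R side): voxel (i,j,k) [0-based] spans
// [i*h,(i+1)*h) x ... ; the fiber axis is z. The substrate is mirrored in z
// (reflective copies), closed in x/y by the exterior label. Per step the
// walker jumps a fixed length sqrt(6 D dt) in a uniformly random direction;
// a step landing in the exterior is reflected specularly off the crossed
// voxel face(s) (elastic reflection; for a z-aligned wall this preserves
// the axial increment exactly), falling back to rejection when the
// reflected point is exterior too (re-entrant voxel corners). A step
// crossing the axoplasm/mitochondrion interface is accepted with
// probability min(1, sqrt(D_to/D_from)) (one-step transit rule for highly
// permeable membranes) with the part of the step beyond the interface
// rescaled by the step-length ratio of the two media — without the rescale
// the endpoint-acceptance walk equilibrates to density ~ 1/sqrt(D) instead
// of uniform — otherwise reflected likewise. Displacements are
// accumulated in the unfolded coordinate, so the mirroring never truncates
// the true path; mirror planes coincide with voxel boundaries, so face
// reflection works directly in unfolded coordinates.
//
// RNG: one splitmix64-seeded xoshiro256+ stream per walker, derived from
// (seed, walker index); results are independent of execution order.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in [0,1)
    return (next() >> 11) * 0x1.0p-53;
  }
};

// Fold z into [0, Lz] under mirror (period-2Lz triangle wave) symmetry.
inline double fold_z(double z, double Lz) {
  const double period = 2.0 * Lz;
  double p = z - period * std::floor(z / period);
  return (p > Lz) ? period - p : p;
}

}  // namespace

// [[Rcpp::export(name = ".walk_cpp")]]
NumericMatrix walk_cpp(IntegerVector labels, IntegerVector dims, double h,
                       NumericVector D, NumericVector invT2, bool use_t2,
                       NumericMatrix init, double dt, int n_steps,
                       IntegerVector sample_steps, double seed_d,
                       bool free_space, double D_free) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double Lz = nz * h;
  const int n_walk = init.nrow();
  const int n_t = sample_steps.size();
  const uint64_t seed = (uint64_t)seed_d;

  // step length and permeation acceptance per (from,to) label pair
  double steplen[3], pacc[3][3];
  for (int l = 0; l < 3; ++l) steplen[l] = std::sqrt(6.0 * D[l] * dt);
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      pacc[a][b] = (D[a] <= 0) ? 0.0
                   : std::min(1.0, std::sqrt(D[b] / D[a]));
  const double step_free = std::sqrt(6.0 * D_free * dt);

  // accumulators: W, n, occ1, occ2, 6 second moments, 15 fourth moments
  const int NC = 4 + 6 + 15;
  std::vector<double> acc((size_t)n_t * NC, 0.0);

  const int *lab = labels.begin();
  // label of the unfolded voxel (ix, iy, izu): z indices are folded with
  // period 2*nz (mirror symmetry), x/y out of range is exterior
  auto label_idx = [&](int ix, int iy, long izu) -> int {
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) return 0;
    long m = izu % (2L * nz);
    if (m < 0) m += 2L * nz;
    int iz = (m >= nz) ? (int)(2L * nz - 1L - m) : (int)m;
    return lab[(size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz)];
  };
  auto label_at = [&](double x, double y, double z) -> int {
    return label_idx((int)std::floor(x / h), (int)std::floor(y / h),
                     (long)std::floor(z / h));
  };
  (void)fold_z;

  for (int w = 0; w < n_walk; ++w) {
    uint64_t sw = seed * 0x9E3779B97f4A7C15ULL + (uint64_t)(w + 1);
    Xoshiro rng(splitmix64(sw));
    double px = init(w, 0), py = init(w, 1), pz = init(w, 2);
    const double ox = px, oy = py, oz = pz;
    int cur = free_space ? 1 : label_at(px, py, pz);
    double logw = 0.0;
    int si = 0;
    for (int step = 1; step <= n_steps && si < n_t; ++step) {
      // Marsaglia (1972) uniform direction on the sphere: no trig calls
      double du, dv, ds;
      do {
        du = 2.0 * rng.unif() - 1.0;
        dv = 2.0 * rng.unif() - 1.0;
        ds = du * du + dv * dv;
      } while (ds >= 1.0);
      const double root = std::sqrt(1.0 - ds);
      const double len = free_space ? step_free : steplen[cur];
      const double qx = px + len * 2.0 * du * root;
      const double qy = py + len * 2.0 * dv * root;
      const double qz = pz + len * (1.0 - 2.0 * ds);
      if (free_space) {
        px = qx; py = qy; pz = qz;
      } else {
        const int lab_q = label_at(qx, qy, qz);
        bool moved = false;
        if (lab_q == cur) {
          px = qx; py = qy; pz = qz;
          moved = true;
        } else if (lab_q != 0 && rng.unif() < pacc[cur][lab_q]) {
          // transmission: rescale the segment beyond the crossed voxel
          // face by the step-length ratio of the destination medium
          const double ratio = steplen[lab_q] / steplen[cur];
          const int ix = (int)std::floor(px / h);
          const int iy = (int)std::floor(py / h);
          const long izu = (long)std::floor(pz / h);
          const int jx = (int)std::floor(qx / h);
          const int jy = (int)std::floor(qy / h);
          const long jzu = (long)std::floor(qz / h);
          // face-crossing parameters along the segment, in order; the
          // compartment changes at the first face beyond which the label
          // (probed at segment midpoints) differs from the current one
          double sc[3];
          int nsc = 0;
          if (jx != ix) sc[nsc++] = (((jx > ix) ? jx : ix) * h - px) / (qx - px);
          if (jy != iy) sc[nsc++] = (((jy > iy) ? jy : iy) * h - py) / (qy - py);
          if (jzu != izu)
            sc[nsc++] = ((double)((jzu > izu) ? jzu : izu) * h - pz) / (qz - pz);
          for (int a = 1; a < nsc; ++a)
            for (int b_ = a; b_ > 0 && sc[b_] < sc[b_ - 1]; --b_)
              std::swap(sc[b_], sc[b_ - 1]);
          double s = (nsc > 0) ? sc[nsc - 1] : 0.0;
          for (int a = 0; a < nsc; ++a) {
            const double smid = 0.5 * (sc[a] + ((a + 1 < nsc) ? sc[a + 1] : 1.0));
            if (label_at(px + smid * (qx - px), py + smid * (qy - py),
                         pz + smid * (qz - pz)) != cur) {
              s = sc[a];
              break;
            }
          }
          if (s < 0.0) s = 0.0;
          if (s > 1.0) s = 1.0;
          const double xx_ = px + s * (qx - px);
          const double xy_ = py + s * (qy - py);
          const double xz_ = pz + s * (qz - pz);
          const double q2x = xx_ + (qx - xx_) * ratio;
          const double q2y = xy_ + (qy - xy_) * ratio;
          const double q2z = xz_ + (qz - xz_) * ratio;
          if (label_at(q2x, q2y, q2z) == lab_q) {
            px = q2x; py = q2y; pz = q2z; cur = lab_q;
            moved = true;
          } else if (label_at(qx, qy, qz) == lab_q) {
            px = qx; py = qy; pz = qz; cur = lab_q;
            moved = true;
          }
        }
        if (!moved) {
          // specular reflection across the crossed voxel face(s); the step
          // length is <= h so index changes are at most one per axis
          const int ix = (int)std::floor(px / h);
          const int iy = (int)std::floor(py / h);
          const long izu = (long)std::floor(pz / h);
          const int jx = (int)std::floor(qx / h);
          const int jy = (int)std::floor(qy / h);
          const long jzu = (long)std::floor(qz / h);
          double rx = qx, ry = qy, rz = qz;
          if (jx > ix) rx = 2.0 * (ix + 1) * h - qx;
          else if (jx < ix) rx = 2.0 * ix * h - qx;
          if (jy > iy) ry = 2.0 * (iy + 1) * h - qy;
          else if (jy < iy) ry = 2.0 * iy * h - qy;
          if (jzu > izu) rz = 2.0 * (double)(izu + 1) * h - qz;
          else if (jzu < izu) rz = 2.0 * (double)izu * h - qz;
          if (label_at(rx, ry, rz) == cur) {
            px = rx; py = ry; pz = rz;
          }  // else: ambiguous corner, walker stays
        }
      }
      if (use_t2) logw -= dt * invT2[cur];
      if (step == sample_steps[si]) {
        const double wgt = use_t2 ? std::exp(logw) : 1.0;
        const double dx = px - ox, dy = py - oy, dz_ = pz - oz;
        double *a = &acc[(size_t)si * NC];
        a[0] += wgt;
        a[1] += 1.0;
        if (cur == 1) a[2] += 1.0; else if (cur == 2) a[3] += 1.0;
        const double xx = dx * dx, yy = dy * dy, zz = dz_ * dz_;
        a[4] += wgt * xx;
        a[5] += wgt * dx * dy;
        a[6] += wgt * dx * dz_;
        a[7] += wgt * yy;
        a[8] += wgt * dy * dz_;
        a[9] += wgt * zz;
        a[10] += wgt * xx * xx;        // xxxx
        a[11] += wgt * xx * dx * dy;   // xxxy
        a[12] += wgt * xx * dx * dz_;  // xxxz
        a[13] += wgt * xx * yy;        // xxyy
        a[14] += wgt * xx * dy * dz_;  // xxyz
        a[15] += wgt * xx * zz;        // xxzz
        a[16] += wgt * dx * yy * dy;   // xyyy
        a[17] += wgt * dx * yy * dz_;  // xyyz
        a[18] += wgt * dx * dy * zz;   // xyzz
        a[19] += wgt * dx * zz * dz_;  // xzzz
        a[20] += wgt * yy * yy;        // yyyy
        a[21] += wgt * yy * dy * dz_;  // yyyz
        a[22] += wgt * yy * zz;        // yyzz
        a[23] += wgt * dy * zz * dz_;  // yzzz
        a[24] += wgt * zz * zz;        // zzzz
        ++si;
      }
    }
    if (w % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(n_t, NC);
  for (int i = 0; i < n_t; ++i)
    for (int j = 0; j < NC; ++j) out(i, j) = acc[(size_t)i * NC + j];
  return out;
}
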