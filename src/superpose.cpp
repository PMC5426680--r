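#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a 3D grid at (x, y, z) in grid coordinates (cm).
// Per-axis out-of-range handling: mode 0 clamps coordinates within half a
// voxel outside the sampled extent to the boundary (then 0 farther out);
// mode 1 zero-pads, so values fall linearly to 0 over one voxel beyond the
// last sample.
static inline double trilinear(const double *v, const int *dim,
                               const double *sp, const double *orig,
                               const int *mode, double x, double y,
                               double z) {
  double f[3] = {(x - orig[0]) / sp[0], (y - orig[1]) / sp[1],
                 (z - orig[2]) / sp[2]};
  int lo[3], hi[3];
  double t[3];
  for (int a = 0; a < 3; ++a) {
    if (mode[a] == 0) {
      if (f[a] < -0.5 || f[a] > dim[a] - 0.5) return 0.0;
      if (f[a] < 0) f[a] = 0;
      else if (f[a] > dim[a] - 1) f[a] = dim[a] - 1;
    } else {
      if (f[a] <= -1.0 || f[a] >= dim[a]) return 0.0;
    }
    lo[a] = (int)std::floor(f[a]);
    hi[a] = lo[a] + 1;
    t[a] = f[a] - lo[a];
  }
  const R_xlen_t sx = 1, sy = dim[0], sz = (R_xlen_t)dim[0] * dim[1];
  double acc = 0.0;
  for (int ck = 0; ck < 2; ++ck) {
    int k = ck ? hi[2] : lo[2];
    double wk = ck ? t[2] : 1 - t[2];
    if (wk == 0 || k < 0 || k > dim[2] - 1) continue;  // zero padding
    for (int cj = 0; cj < 2; ++cj) {
      int j = cj ? hi[1] : lo[1];
      double wj = cj ? t[1] : 1 - t[1];
      if (wj == 0 || j < 0 || j > dim[1] - 1) continue;
      for (int ci = 0; ci < 2; ++ci) {
        int i = ci ? hi[0] : lo[0];
        double wi = ci ? t[0] : 1 - t[0];
        if (wi == 0 || i < 0 || i > dim[0] - 1) continue;
        acc += wi * wj * wk * v[i * sx + j * sy + k * sz];
      }
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector sample_grid_cpp(NumericVector values, IntegerVector dim,
                              NumericVector spacing, NumericVector origin,
                              NumericMatrix points) {
  int n = points.nrow();
  NumericVector out(n);
  int d[3] = {dim[0], dim[1], dim[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double orig[3] = {origin[0], origin[1], origin[2]};
  const int clamp_all[3] = {0, 0, 0};
  const double *v = values.begin();
  for (int i = 0; i < n; ++i) {
    out[i] = trilinear(v, d, sp, orig, clamp_all, points(i, 0), points(i, 1),
                       points(i, 2));
  }
  return out;
}

// Accumulate a beam-frame kernel into a phantom-frame grid over a set of
// placements. placements: n x 7 matrix (entry xyz, unit direction xyz,
// weight). For each placement the kernel depth axis lies along the beam
// direction with z = 0 at the entry point; the two lateral axes are an
// arbitrary orthonormal completion (kernels are x/y symmetric).
// [[Rcpp::export]]
NumericVector superpose_cpp(NumericVector kernel, IntegerVector kdim,
                            NumericVector kspacing, NumericVector korigin,
                            NumericMatrix placements, IntegerVector pdim,
                            NumericVector pspacing, NumericVector porigin) {
  int kd[3] = {kdim[0], kdim[1], kdim[2]};
  double ksp[3] = {kspacing[0], kspacing[1], kspacing[2]};
  double korig[3] = {korigin[0], korigin[1], korigin[2]};
  const double *kv = kernel.begin();
  const int nx = pdim[0], ny = pdim[1], nz = pdim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *ov = out.begin();

  // kernel support bounds in beam coordinates: laterally the kernel is
  // truncated and zero-padded, so values fall to 0 within one voxel past
  // the outermost sample; along depth a half-voxel clamp halo is kept (the
  // surface plane holds ~zero dose, the deep end the flat tail)
  const int kmode[3] = {1, 1, 0};
  double kxlo = korig[0] - ksp[0];
  double kxhi = korig[0] + kd[0] * ksp[0];
  double kylo = korig[1] - ksp[1];
  double kyhi = korig[1] + kd[1] * ksp[1];
  double kzlo = korig[2] - 0.5 * ksp[2];
  double kzhi = korig[2] + (kd[2] - 0.5) * ksp[2];

  int nplace = placements.nrow();
  for (int b = 0; b < nplace; ++b) {
    double ex = placements(b, 0), ey = placements(b, 1), ez = placements(b, 2);
    double wx = placements(b, 3), wy = placements(b, 4), wz = placements(b, 5);
    double wt = placements(b, 6);
    // orthonormal lateral axes: u = w x a with a the world axis least
    // aligned with w, v = w x u
    double ax = 0, ay = 0, az = 0;
    double aw[3] = {std::fabs(wx), std::fabs(wy), std::fabs(wz)};
    if (aw[0] <= aw[1] && aw[0] <= aw[2]) ax = 1;
    else if (aw[1] <= aw[2]) ay = 1;
    else az = 1;
    double ux = wy * az - wz * ay, uy = wz * ax - wx * az,
           uz = wx * ay - wy * ax;
    double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= un; uy /= un; uz /= un;
    double vx = wy * uz - wz * uy, vy = wz * ux - wx * uz,
           vz = wx * uy - wy * ux;

    // axis-aligned bounding box of the transformed kernel support
    double lo[3], hi[3];
    const double uu[3] = {ux, uy, uz}, vv[3] = {vx, vy, vz},
                 ww[3] = {wx, wy, wz};
    const double ee[3] = {ex, ey, ez};
    for (int c = 0; c < 3; ++c) {
      double span = std::fabs(uu[c]) * std::max(std::fabs(kxlo), std::fabs(kxhi)) +
                    std::fabs(vv[c]) * std::max(std::fabs(kylo), std::fabs(kyhi));
      double zmin = ww[c] * kzlo, zmax = ww[c] * kzhi;
      if (zmin > zmax) { double t = zmin; zmin = zmax; zmax = t; }
      lo[c] = ee[c] - span + zmin;
      hi[c] = ee[c] + span + zmax;
    }
    int i0 = (int)std::ceil((lo[0] - porigin[0]) / pspacing[0]);
    int i1 = (int)std::floor((hi[0] - porigin[0]) / pspacing[0]);
    int j0 = (int)std::ceil((lo[1] - porigin[1]) / pspacing[1]);
    int j1 = (int)std::floor((hi[1] - porigin[1]) / pspacing[1]);
    int k0 = (int)std::ceil((lo[2] - porigin[2]) / pspacing[2]);
    int k1 = (int)std::floor((hi[2] - porigin[2]) / pspacing[2]);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;

    for (int k = k0; k <= k1; ++k) {
      double pz = porigin[2] + k * pspacing[2] - ez;
      for (int j = j0; j <= j1; ++j) {
        double py = porigin[1] + j * pspacing[1] - ey;
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = i0; i <= i1; ++i) {
          double px = porigin[0] + i * pspacing[0] - ex;
          double bz = px * wx + py * wy + pz * wz;
          if (bz < kzlo || bz > kzhi) continue;
          double bx = px * ux + py * uy + pz * uz;
          if (bx < kxlo || bx > kxhi) continue;
          double by = px * vx + py * vy + pz * vz;
          if (by < kylo || by > kyhi) continue;
          double val = trilinear(kv, kd, ksp, korig, kmode, bx, by, bz);
          if (val > 0) ov[base + i] += wt * val;
        }
      }
    }
    if (b % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
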