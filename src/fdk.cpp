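// Voxel-driven distance-weighted FDK backprojection for a circular orbit
// in the rotating-phantom frame.
#include <RcppArmadillo.h>
using namespace Rcpp;

// projs: filtered projections, nu x nv x na (u along detector rows at
// isocenter scale du_iso, v along the rotation axis at dv_iso).
// angles in radians; beam direction at angle b is (cos b, sin b, 0),
// source at -sad * dir. Returns vol_dim volume (1/cm if projections are
// dimensionless line integrals filtered on a cm-consistent grid; here
// everything is mm and the caller rescales).
// [[Rcpp::export]]
NumericVector cpp_fdk_backproject(NumericVector projs, IntegerVector pdims,
                                  NumericVector angles, double sad,
                                  double du_iso, double dv_iso,
                                  IntegerVector vol_dim, NumericVector voxel,
                                  NumericVector vol_origin) {
  const int nu = pdims[0], nv = pdims[1], na = pdims[2];
  const int nx = vol_dim[0], ny = vol_dim[1], nz = vol_dim[2];
  NumericVector vol((size_t)nx * ny * nz);
  vol.attr("dim") = vol_dim;
  const double dbeta = 2.0 * M_PI / na;
  const double ucen = (nu - 1) / 2.0, vcen = (nv - 1) / 2.0;
  const double* P = projs.begin();
  double* V = vol.begin();

  for (int a = 0; a < na; ++a) {
    const double cb = std::cos(angles[a]), sb = std::sin(angles[a]);
    const double sx = -sad * cb, sy = -sad * sb;
    const double* Pa = P + (size_t)a * nu * nv;
    for (int iz = 0; iz < nz; ++iz) {
      const double z = vol_origin[2] + (iz + 0.5) * voxel[2];
      for (int iy = 0; iy < ny; ++iy) {
        const double y = vol_origin[1] + (iy + 0.5) * voxel[1];
        size_t base = (size_t)nx * (iy + (size_t)ny * iz);
        for (int ix = 0; ix < nx; ++ix) {
          const double x = vol_origin[0] + (ix + 0.5) * voxel[0];
          const double qx = x - sx, qy = y - sy;
          const double U = qx * cb + qy * sb;      // distance along beam
          if (U <= 1e-6) continue;
          const double uu = (-qx * sb + qy * cb) * sad / U;
          const double vv = z * sad / U;
          const double fu = uu / du_iso + ucen, fv = vv / dv_iso + vcen;
          const int iu = (int)std::floor(fu), iv = (int)std::floor(fv);
          if (iu < 0 || iu >= nu - 1 || iv < 0 || iv >= nv - 1) continue;
          const double au = fu - iu, av = fv - iv;
          const double p00 = Pa[iu + nu * iv], p10 = Pa[iu + 1 + nu * iv];
          const double p01 = Pa[iu + nu * (iv + 1)],
                       p11 = Pa[iu + 1 + nu * (iv + 1)];
          const double val = (1 - au) * ((1 - av) * p00 + av * p01) +
                             au * ((1 - av) * p10 + av * p11);
          V[base + ix] += dbeta * sad * sad / (U * U) * val;
        }
      }
    }
  }
  return vol;
}
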