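// Exact radiological path lengths through a regular voxel grid
// (incremental Siddon / Amanatides-Woo traversal).
#include <RcppArmadillo.h>
using namespace Rcpp;

// labels: nx*ny*nz integer grid (label 0 = air); voxel/origin/src/pix in mm.
// Returns npix x (nlab+1) matrix of per-label intersection lengths in cm;
// column j holds label j-1.
// [[Rcpp::export]]
NumericMatrix cpp_siddon(IntegerVector labels, IntegerVector dims,
                         NumericVector voxel, NumericVector origin,
                         NumericVector src, NumericMatrix pix, int nlab) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = voxel[0], hy = voxel[1], hz = voxel[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int npix = pix.nrow();
  NumericMatrix out(npix, nlab + 1);
  const double gx1 = ox + nx * hx, gy1 = oy + ny * hy, gz1 = oz + nz * hz;
  const int* lab = labels.begin();

  for (int p = 0; p < npix; ++p) {
    double dx = pix(p, 0) - src[0], dy = pix(p, 1) - src[1],
           dz = pix(p, 2) - src[2];
    double raylen = std::sqrt(dx * dx + dy * dy + dz * dz);
    // slab intersection, parametrized t in [0,1] from source to pixel
    double tmin = 0.0, tmax = 1.0;
    const double d[3] = {dx, dy, dz};
    const double s[3] = {src[0], src[1], src[2]};
    const double g0[3] = {ox, oy, oz}, g1[3] = {gx1, gy1, gz1};
    bool miss = false;
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-12) {
        if (s[a] < g0[a] || s[a] > g1[a]) { miss = true; break; }
      } else {
        double t0 = (g0[a] - s[a]) / d[a], t1 = (g1[a] - s[a]) / d[a];
        if (t0 > t1) std::swap(t0, t1);
        tmin = std::max(tmin, t0);
        tmax = std::min(tmax, t1);
      }
    }
    if (miss || tmin >= tmax) continue;

    // entry voxel
    double px = s[0] + tmin * dx, py = s[1] + tmin * dy, pz = s[2] + tmin * dz;
    int ix = (int)std::floor((px - ox) / hx);
    int iy = (int)std::floor((py - oy) / hy);
    int iz = (int)std::floor((pz - oz) / hz);
    ix = std::min(std::max(ix, 0), nx - 1);
    iy = std::min(std::max(iy, 0), ny - 1);
    iz = std::min(std::max(iz, 0), nz - 1);

    const int stepx = (dx > 0) - (dx < 0);
    const int stepy = (dy > 0) - (dy < 0);
    const int stepz = (dz > 0) - (dz < 0);
    const double big = std::numeric_limits<double>::infinity();
    double tx = big, ty = big, tz = big, dtx = big, dty = big, dtz = big;
    if (stepx != 0) {
      double bnd = ox + (ix + (stepx > 0)) * hx;
      tx = (bnd - s[0]) / dx; dtx = hx / std::fabs(dx);
    }
    if (stepy != 0) {
      double bnd = oy + (iy + (stepy > 0)) * hy;
      ty = (bnd - s[1]) / dy; dty = hy / std::fabs(dy);
    }
    if (stepz != 0) {
      double bnd = oz + (iz + (stepz > 0)) * hz;
      tz = (bnd - s[2]) / dz; dtz = hz / std::fabs(dz);
    }

    double t = tmin;
    while (t < tmax - 1e-12) {
      double tnext = std::min(std::min(tx, ty), std::min(tz, tmax));
      int l = lab[ix + (size_t)nx * (iy + (size_t)ny * iz)];
      if (l >= 0 && l <= nlab)
        out(p, l) += (tnext - t) * raylen * 0.1;  // mm -> cm
      t = tnext;
      if (t >= tmax - 1e-12) break;
      if (tx <= ty && tx <= tz) {
        ix += stepx; tx += dtx;
        if (ix < 0 || ix >= nx) break;
      } else if (ty <= tz) {
        iy += stepy; ty += dty;
        if (iy < 0 || iy >= ny) break;
      } else {
        iz += stepz; tz += dtz;
        if (iz < 0 || iz >= nz) break;
      }
    }
  }
  return out;
}

// 6-connectivity flood fill; component ids returned in decreasing size order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask) {
  IntegerVector dims = mask.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector out(mask.size());
  out.attr("dim") = dims;
  std::vector<size_t> stack, sizes;
  int comp = 0;
  for (size_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || out[i] != 0) continue;
    ++comp;
    size_t sz = 0;
    stack.push_back(i);
    out[i] = comp;
    while (!stack.empty()) {
      size_t v = stack.back(); stack.pop_back();
      ++sz;
      int ix = v % nx, iy = (v / nx) % ny, iz = v / ((size_t)nx * ny);
      const int nb[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (auto& d : nb) {
        int jx = ix + d[0], jy = iy + d[1], jz = iz + d[2];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
          continue;
        size_t j = jx + (size_t)nx * (jy + (size_t)ny * jz);
        if (mask[j] != 0 && out[j] == 0) { out[j] = comp; stack.push_back(j); }
      }
    }
    sizes.push_back(sz);
  }
  // relabel by decreasing size
  std::vector<int> order(comp);
  for (int c = 0; c < comp; ++c) order[c] = c;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> remap(comp + 1, 0);
  for (int r = 0; r < comp; ++r) remap[order[r] + 1] = r + 1;
  for (size_t i = 0; i < n; ++i) out[i] = remap[out[i]];
  return out;
}
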