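#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Exact radiological path integral of a voxelized attenuation volume along
// source->detector-pixel rays (Siddon's incremental traversal). The volume is
// piecewise constant over voxels; voxel boundaries lie half a spacing outside
// the voxel-centre lattice. Lengths in mm, result dimensionless (mm^-1 * mm).
//
// vol:    nx*ny*nz attenuation values, x fastest (R array layout)
// dims:   c(nx, ny, nz)
// origin: world position of the centre of voxel (1,1,1)
// spacing: mm per voxel
// src:    source position (3)
// px, py, pz: per-pixel detector positions (nu*nv each)
// [[Rcpp::export(name = ".siddon_project_cpp")]]
NumericVector siddon_project_cpp(NumericVector vol, IntegerVector dims,
                                 NumericVector origin, NumericVector spacing,
                                 NumericVector src,
                                 NumericVector px, NumericVector py,
                                 NumericVector pz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // box boundaries (outer faces of the voxel lattice)
  const double bx0 = origin[0] - 0.5 * sx, bx1 = bx0 + nx * sx;
  const double by0 = origin[1] - 0.5 * sy, by1 = by0 + ny * sy;
  const double bz0 = origin[2] - 0.5 * sz, bz1 = bz0 + nz * sz;
  const double s0 = src[0], s1 = src[1], s2 = src[2];
  const R_xlen_t np = px.size();
  NumericVector out(np);

  for (R_xlen_t p = 0; p < np; ++p) {
    const double dx = px[p] - s0, dy = py[p] - s1, dz = pz[p] - s2;
    const double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    // slab clipping to [amin, amax] in ray parameter alpha in [0,1]
    double amin = 0.0, amax = 1.0;
    const double d[3] = {dx, dy, dz};
    const double s[3] = {s0, s1, s2};
    const double b0[3] = {bx0, by0, bz0};
    const double b1[3] = {bx1, by1, bz1};
    bool miss = false;
    for (int ax = 0; ax < 3; ++ax) {
      if (std::fabs(d[ax]) < 1e-12) {
        if (s[ax] <= b0[ax] || s[ax] >= b1[ax]) { miss = true; break; }
      } else {
        double a0 = (b0[ax] - s[ax]) / d[ax];
        double a1 = (b1[ax] - s[ax]) / d[ax];
        if (a0 > a1) std::swap(a0, a1);
        amin = std::max(amin, a0);
        amax = std::min(amax, a1);
      }
    }
    if (miss || amin >= amax) { out[p] = 0.0; continue; }

    // entry point and initial voxel indices (0-based)
    const double eps = 1e-10;
    double acur = amin;
    const double exx = s0 + amin * dx, exy = s1 + amin * dy, exz = s2 + amin * dz;
    int ix = (int)std::floor((exx - bx0) / sx);
    int iy = (int)std::floor((exy - by0) / sy);
    int iz = (int)std::floor((exz - bz0) / sz);
    ix = std::min(std::max(ix, 0), nx - 1);
    iy = std::min(std::max(iy, 0), ny - 1);
    iz = std::min(std::max(iz, 0), nz - 1);

    // alpha of the next boundary crossing and per-voxel increments per axis
    const int stepx = (dx > 0) - (dx < 0);
    const int stepy = (dy > 0) - (dy < 0);
    const int stepz = (dz > 0) - (dz < 0);
    const double dax = (std::fabs(dx) > 1e-12) ? sx / std::fabs(dx) : R_PosInf;
    const double day = (std::fabs(dy) > 1e-12) ? sy / std::fabs(dy) : R_PosInf;
    const double daz = (std::fabs(dz) > 1e-12) ? sz / std::fabs(dz) : R_PosInf;
    double ax_next, ay_next, az_next;
    if (stepx != 0) {
      const double bnext = bx0 + (ix + (stepx > 0 ? 1 : 0)) * sx;
      ax_next = (bnext - s0) / dx;
    } else ax_next = R_PosInf;
    if (stepy != 0) {
      const double bnext = by0 + (iy + (stepy > 0 ? 1 : 0)) * sy;
      ay_next = (bnext - s1) / dy;
    } else ay_next = R_PosInf;
    if (stepz != 0) {
      const double bnext = bz0 + (iz + (stepz > 0 ? 1 : 0)) * sz;
      az_next = (bnext - s2) / dz;
    } else az_next = R_PosInf;

    double acc = 0.0;
    while (acur < amax - eps) {
      const double anext = std::min(std::min(ax_next, ay_next),
                                    std::min(az_next, amax));
      const double seg = (anext - acur) * len;
      if (seg > 0) {
        acc += seg * vol[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
      }
      acur = anext;
      if (acur >= amax - eps) break;
      if (ax_next <= ay_next && ax_next <= az_next) {
        ix += stepx; ax_next += dax;
        if (ix < 0 || ix >= nx) break;
      } else if (ay_next <= az_next) {
        iy += stepy; ay_next += day;
        if (iy < 0 || iy >= ny) break;
      } else {
        iz += stepz; az_next += daz;
        if (iz < 0 || iz >= nz) break;
      }
    }
    out[p] = acc;
  }
  return out;
}
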