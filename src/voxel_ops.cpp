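#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>
using namespace Rcpp;

// Voxel grids are R arrays of type raw, column-major with dim = (nx, ny, nz).
// Voxel (i,j,k) (0-based) has its center at origin + (i+0.5, j+0.5, k+0.5)*h.

static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Paint the arterial wall: a shell of revolution about the canonical z axis
// whose rim height varies with azimuth (tilted commissure circle) and whose
// radius interpolates linearly from r_anl at z = 0 to r_stj at the rim.
// rot (3x3, row-major as R matrix) maps world -> canonical: p_can = rot %*% (p - center).
// [[Rcpp::export]]
void cpp_paint_wall(RawVector grid, IntegerVector dim, NumericVector origin,
                    double h, NumericMatrix rot, NumericVector center,
                    double r_anl, double r_stj, double h0, double tanb,
                    double psi_tilt, double wall_thick, double z_bot,
                    int label) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double ht = wall_thick / 2.0;
  for (int k = 0; k < nz; ++k) {
    const double wz = origin[2] + (k + 0.5) * h;
    for (int j = 0; j < ny; ++j) {
      const double wy = origin[1] + (j + 0.5) * h;
      for (int i = 0; i < nx; ++i) {
        const double wx = origin[0] + (i + 0.5) * h;
        const double px = wx - center[0], py = wy - center[1], pz = wz - center[2];
        const double x = rot(0,0)*px + rot(0,1)*py + rot(0,2)*pz;
        const double y = rot(1,0)*px + rot(1,1)*py + rot(1,2)*pz;
        const double z = rot(2,0)*px + rot(2,1)*py + rot(2,2)*pz;
        if (z < z_bot) continue;
        const double psi = std::atan2(y, x);
        const double ztop = h0 + r_stj * tanb * (1.0 - std::cos(psi - psi_tilt));
        if (z > ztop) continue;
        const double r = std::sqrt(x*x + y*y);
        const double rw = r_anl + (r_stj - r_anl) * (z / ztop);
        if (std::fabs(r - rw) <= ht) {
          R_xlen_t id = lin(i, j, k, nx, ny);
          if (grid[id] == 0) grid[id] = (Rbyte)label;
        }
      }
    }
  }
}

// Stamp a thickened surface into the grid: for each sample point with unit
// normal, walk the normal segment [-half_thick, half_thick] and mark the
// voxels hit -- but only when the voxel CENTER lies within half_thick of the
// local tangent plane, so the label obeys the same center-inside-object
// semantics as a segmentation of the continuum object.
// Overwrites background and (optionally) the wall label, never other labels.
// [[Rcpp::export]]
void cpp_stamp_points(RawVector grid, IntegerVector dim, NumericVector origin,
                      double h, NumericMatrix pts, NumericMatrix nrm,
                      double half_thick, double step, int label,
                      int wall_label) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t npts = pts.nrow();
  const int nstep = (int)std::ceil(half_thick / step);
  for (R_xlen_t p = 0; p < npts; ++p) {
    const double x0 = pts(p,0), y0 = pts(p,1), z0 = pts(p,2);
    const double ux = nrm(p,0), uy = nrm(p,1), uz = nrm(p,2);
    for (int s = -nstep; s <= nstep; ++s) {
      double t = s * step;
      if (t < -half_thick) t = -half_thick;
      if (t >  half_thick) t =  half_thick;
      const double x = x0 + t*ux, y = y0 + t*uy, z = z0 + t*uz;
      const int i = (int)std::floor((x - origin[0]) / h);
      const int j = (int)std::floor((y - origin[1]) / h);
      const int k = (int)std::floor((z - origin[2]) / h);
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
      const double cx = origin[0] + (i + 0.5) * h - x0;
      const double cy = origin[1] + (j + 0.5) * h - y0;
      const double cz = origin[2] + (k + 0.5) * h - z0;
      if (std::fabs(cx*ux + cy*uy + cz*uz) > half_thick) continue;
      R_xlen_t id = lin(i, j, k, nx, ny);
      const Rbyte cur = grid[id];
      if (cur == 0 || (int)cur == wall_label) grid[id] = (Rbyte)label;
    }
  }
}

// ---- exact Euclidean distance transform (squared), separable lower-envelope ----

static void edt1d(const std::vector<float>& f, std::vector<float>& d,
                  std::vector<int>& v, std::vector<float>& z, int n) {
  const float INF = std::numeric_limits<float>::max() / 4.0f;
  int kk = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    float s;
    while (true) {
      s = ((f[q] + q*(float)q) - (f[v[kk]] + v[kk]*(float)v[kk])) / (2.0f*q - 2.0f*v[kk]);
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk+1] = INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk+1] < q) ++kk;
    const float dq = q - (float)v[kk];
    d[q] = dq*dq + f[v[kk]];
  }
}

static void edt3d(std::vector<float>& D, int nx, int ny, int nz) {
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<float> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = lin(0, j, k, nx, ny);
      for (int i = 0; i < nx; ++i) f[i] = D[base + i];
      edt1d(f, d, v, z, nx);
      for (int i = 0; i < nx; ++i) D[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = D[lin(i, j, k, nx, ny)];
      edt1d(f, d, v, z, ny);
      for (int j = 0; j < ny; ++j) D[lin(i, j, k, nx, ny)] = d[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = D[lin(i, j, k, nx, ny)];
      edt1d(f, d, v, z, nz);
      for (int k = 0; k < nz; ++k) D[lin(i, j, k, nx, ny)] = d[k];
    }
}

// Distance transform of one label plus mid-surface ridge voxels.
// Returns distances in voxel units (to the nearest non-label voxel center).
// A ridge voxel is a local EDT maximum along at least one of the 13 axis
// pairs of the 26-neighborhood, with EDT >= ridge_frac * max(EDT).
// [[Rcpp::export]]
List cpp_midsurface(RawVector grid, IntegerVector dim, int label,
                    double ridge_frac) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const float INF = std::numeric_limits<float>::max() / 4.0f;
  std::vector<float> D(n);
  for (R_xlen_t t = 0; t < n; ++t) D[t] = ((int)grid[t] == label) ? INF : 0.0f;
  edt3d(D, nx, ny, nz);
  float dmax2 = 0.0f;
  for (R_xlen_t t = 0; t < n; ++t)
    if ((int)grid[t] == label && D[t] > dmax2) dmax2 = D[t];
  const float thr2 = (float)(ridge_frac * ridge_frac) * dmax2;
  static const int pairs[13][3] = {
    {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
    {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
  std::vector<int> ridx;
  std::vector<double> rdist;
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        const R_xlen_t id = lin(i, j, k, nx, ny);
        if ((int)grid[id] != label) continue;
        const float d0sq = D[id];
        if (d0sq < thr2) continue;
        // thickness direction = axis pair with the smallest neighbor sum of
        // (unsquared) distances; a mid-surface voxel is a local max along
        // that pair, and the pair must genuinely descend (by half a voxel
        // over the two sides) -- in-plane plateau pairs of the slab interior
        // tie at 2*d0 and are rejected
        const float d0 = std::sqrt(d0sq);
        float dbp = 0.0f, dbm = 0.0f;
        float bestsum = std::numeric_limits<float>::max();
        for (int p = 0; p < 13; ++p) {
          const R_xlen_t ip = lin(i + pairs[p][0], j + pairs[p][1], k + pairs[p][2], nx, ny);
          const R_xlen_t im = lin(i - pairs[p][0], j - pairs[p][1], k - pairs[p][2], nx, ny);
          const float dp = std::sqrt(D[ip]), dm = std::sqrt(D[im]);
          if (dp + dm < bestsum) { bestsum = dp + dm; dbp = dp; dbm = dm; }
        }
        if (bestsum <= 2.0f * d0 - 0.5f && d0 >= dbp && d0 >= dbm) {
          ridx.push_back((int)(id + 1));  // 1-based for R
          rdist.push_back((double)d0);
        }
      }
  return List::create(_["idx"] = wrap(ridx), _["dist_vox"] = wrap(rdist),
                      _["max_dist_vox"] = std::sqrt((double)dmax2));
}

// Indices (1-based) of voxels with label lab_self having at least one
// 26-neighbor with label lab_near.
// [[Rcpp::export]]
IntegerVector cpp_adjacency(RawVector grid, IntegerVector dim, int lab_self,
                            int lab_near) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> out;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t id = lin(i, j, k, nx, ny);
        if ((int)grid[id] != lab_self) continue;
        bool hit = false;
        for (int dk = -1; dk <= 1 && !hit; ++dk) {
          const int k2 = k + dk;
          if (k2 < 0 || k2 >= nz) continue;
          for (int dj = -1; dj <= 1 && !hit; ++dj) {
            const int j2 = j + dj;
            if (j2 < 0 || j2 >= ny) continue;
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              const int i2 = i + di;
              if (i2 < 0 || i2 >= nx) continue;
              if ((int)grid[lin(i2, j2, k2, nx, ny)] == lab_near) { hit = true; break; }
            }
          }
        }
        if (hit) out.push_back((int)(id + 1));
      }
  return wrap(out);
}

// 1-based linear indices of all voxels carrying a label.
// [[Rcpp::export]]
IntegerVector cpp_which_label(RawVector grid, IntegerVector dim, int label) {
  const R_xlen_t n = (R_xlen_t)dim[0] * dim[1] * dim[2];
  std::vector<int> out;
  for (R_xlen_t t = 0; t < n; ++t)
    if ((int)grid[t] == label) out.push_back((int)(t + 1));
  return wrap(out);
}

// First and second coordinate moments (world coordinates) of a label.
// [[Rcpp::export]]
List cpp_label_moments(RawVector grid, IntegerVector dim, int label,
                       NumericVector origin, double h) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double n = 0.0, sx = 0.0, sy = 0.0, sz = 0.0;
  double sxx = 0.0, sxy = 0.0, sxz = 0.0, syy = 0.0, syz = 0.0, szz = 0.0;
  for (int k = 0; k < nz; ++k) {
    const double z = origin[2] + (k + 0.5) * h;
    for (int j = 0; j < ny; ++j) {
      const double y = origin[1] + (j + 0.5) * h;
      for (int i = 0; i < nx; ++i) {
        if ((int)grid[lin(i, j, k, nx, ny)] != label) continue;
        const double x = origin[0] + (i + 0.5) * h;
        n += 1.0; sx += x; sy += y; sz += z;
        sxx += x*x; sxy += x*y; sxz += x*z;
        syy += y*y; syz += y*z; szz += z*z;
      }
    }
  }
  NumericVector s = NumericVector::create(sx, sy, sz);
  NumericMatrix S2(3, 3);
  S2(0,0)=sxx; S2(0,1)=sxy; S2(0,2)=sxz;
  S2(1,0)=sxy; S2(1,1)=syy; S2(1,2)=syz;
  S2(2,0)=sxz; S2(2,1)=syz; S2(2,2)=szz;
  return List::create(_["n"] = n, _["sum"] = s, _["sumsq"] = S2);
}

// Inclusive 0-based bounding box (i0,i1,j0,j1,k0,k1) of a label, or -1s if absent.
// [[Rcpp::export]]
IntegerVector cpp_label_bbox(RawVector grid, IntegerVector dim, int label) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int i0 = nx, i1 = -1, j0 = ny, j1 = -1, k0 = nz, k1 = -1;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if ((int)grid[lin(i, j, k, nx, ny)] == label) {
          if (i < i0) i0 = i; if (i > i1) i1 = i;
          if (j < j0) j0 = j; if (j > j1) j1 = j;
          if (k < k0) k0 = k; if (k > k1) k1 = k;
        }
  if (i1 < 0) return IntegerVector::create(-1, -1, -1, -1, -1, -1);
  return IntegerVector::create(i0, i1, j0, j1, k0, k1);
}

// Crop a padded sub-grid keeping only `label` voxels (everything else 0).
// Returns the raw sub-array, its dim, and the 0-based offset of its corner.
// [[Rcpp::export]]
List cpp_crop_label(RawVector grid, IntegerVector dim, int label, int pad) {
  IntegerVector bb = cpp_label_bbox(grid, dim, label);
  if (bb[1] < 0) stop("label %d not present in volume", label);
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int i0 = std::max(0, bb[0] - pad), i1 = std::min(nx - 1, bb[1] + pad);
  const int j0 = std::max(0, bb[2] - pad), j1 = std::min(ny - 1, bb[3] + pad);
  const int k0 = std::max(0, bb[4] - pad), k1 = std::min(nz - 1, bb[5] + pad);
  const int mx = i1 - i0 + 1, my = j1 - j0 + 1, mz = k1 - k0 + 1;
  RawVector sub((R_xlen_t)mx * my * mz);
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        const Rbyte val = grid[lin(i + i0, j + j0, k + k0, nx, ny)];
        sub[lin(i, j, k, mx, my)] = ((int)val == label) ? (Rbyte)label : (Rbyte)0;
      }
  return List::create(_["grid"] = sub,
                      _["dim"] = IntegerVector::create(mx, my, mz),
                      _["offset"] = IntegerVector::create(i0, j0, k0));
}
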