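// Low-level voxel-grid operations shared by map handling, simulation and
// scoring. Grids are stored x-fastest (R array with dim c(nx, ny, nz));
// physical position of voxel (ix,iy,iz) (0-based here, 1-based in R) is
// origin + c(ix,iy,iz) * voxel.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline long idx3(int ix, int iy, int iz, int nx, int ny) {
  return (long)ix + (long)nx * ((long)iy + (long)ny * (long)iz);
}

// Sum of isotropic Gaussians, one per atom, truncated at cutoff_sigma*sigma.
// The kernel is separable: contributions are products of three 1-D factors.
// [[Rcpp::export]]
NumericVector cpp_sim_density(NumericMatrix coords, NumericVector amp,
                              double sigma, IntegerVector dim,
                              NumericVector origin, double voxel,
                              double cutoff_sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((long)nx * ny * nz);
  const double rcut = cutoff_sigma * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<double> wx, wy, wz;
  for (int a = 0; a < coords.nrow(); ++a) {
    const double cx = (coords(a, 0) - origin[0]) / voxel;
    const double cy = (coords(a, 1) - origin[1]) / voxel;
    const double cz = (coords(a, 2) - origin[2]) / voxel;
    const double rv = rcut / voxel;
    const int x0 = std::max(0, (int)std::ceil(cx - rv)),
              x1 = std::min(nx - 1, (int)std::floor(cx + rv));
    const int y0 = std::max(0, (int)std::ceil(cy - rv)),
              y1 = std::min(ny - 1, (int)std::floor(cy + rv));
    const int z0 = std::max(0, (int)std::ceil(cz - rv)),
              z1 = std::min(nz - 1, (int)std::floor(cz + rv));
    if (x0 > x1 || y0 > y1 || z0 > z1) continue;
    wx.resize(x1 - x0 + 1); wy.resize(y1 - y0 + 1); wz.resize(z1 - z0 + 1);
    for (int i = x0; i <= x1; ++i) {
      double d = (i - cx) * voxel; wx[i - x0] = std::exp(-d * d * inv2s2);
    }
    for (int j = y0; j <= y1; ++j) {
      double d = (j - cy) * voxel; wy[j - y0] = std::exp(-d * d * inv2s2);
    }
    for (int k = z0; k <= z1; ++k) {
      double d = (k - cz) * voxel; wz[k - z0] = std::exp(-d * d * inv2s2);
    }
    const double A = amp[a];
    for (int k = z0; k <= z1; ++k) {
      const double Az = A * wz[k - z0];
      for (int j = y0; j <= y1; ++j) {
        const double Azy = Az * wy[j - y0];
        double *row = REAL(out) + idx3(x0, j, k, nx, ny);
        const double *w = &wx[0];
        for (int i = 0; i <= x1 - x0; ++i) row[i] += Azy * w[i];
      }
    }
  }
  return out;
}

// Trilinear resampling onto a new lattice; positions outside the source grid
// contribute zero.
// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector grid, IntegerVector dim,
                                     NumericVector origin, double voxel,
                                     IntegerVector odim, NumericVector oorigin,
                                     double ovoxel) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = odim[0], my = odim[1], mz = odim[2];
  NumericVector out((long)mx * my * mz);
  const double *g = REAL(grid);
  double *o = REAL(out);
  for (int k = 0; k < mz; ++k) {
    const double pz = (oorigin[2] + k * ovoxel - origin[2]) / voxel;
    for (int j = 0; j < my; ++j) {
      const double py = (oorigin[1] + j * ovoxel - origin[1]) / voxel;
      for (int i = 0; i < mx; ++i) {
        const double px = (oorigin[0] + i * ovoxel - origin[0]) / voxel;
        const int ix = (int)std::floor(px), iy = (int)std::floor(py),
                  iz = (int)std::floor(pz);
        const double fx = px - ix, fy = py - iy, fz = pz - iz;
        double v = 0.0;
        for (int dz = 0; dz <= 1; ++dz) {
          const int z = iz + dz;
          if (z < 0 || z >= nz) continue;
          const double wz = dz ? fz : 1.0 - fz;
          for (int dy = 0; dy <= 1; ++dy) {
            const int y = iy + dy;
            if (y < 0 || y >= ny) continue;
            const double wy = dy ? fy : 1.0 - fy;
            for (int dx = 0; dx <= 1; ++dx) {
              const int x = ix + dx;
              if (x < 0 || x >= nx) continue;
              const double wx = dx ? fx : 1.0 - fx;
              v += wz * wy * wx * g[idx3(x, y, z, nx, ny)];
            }
          }
        }
        o[idx3(i, j, k, mx, my)] = v;
      }
    }
  }
  return out;
}

// Zero every voxel whose center lies within `radius` of any coordinate.
// [[Rcpp::export]]
NumericVector cpp_mask_coords(NumericVector grid, IntegerVector dim,
                              NumericVector origin, double voxel,
                              NumericMatrix coords, double radius) {
  NumericVector out = clone(grid);
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double r2 = radius * radius;
  double *g = REAL(out);
  for (int a = 0; a < coords.nrow(); ++a) {
    const double cx = (coords(a, 0) - origin[0]) / voxel;
    const double cy = (coords(a, 1) - origin[1]) / voxel;
    const double cz = (coords(a, 2) - origin[2]) / voxel;
    const double rv = radius / voxel;
    const int x0 = std::max(0, (int)std::ceil(cx - rv)),
              x1 = std::min(nx - 1, (int)std::floor(cx + rv));
    const int y0 = std::max(0, (int)std::ceil(cy - rv)),
              y1 = std::min(ny - 1, (int)std::floor(cy + rv));
    const int z0 = std::max(0, (int)std::ceil(cz - rv)),
              z1 = std::min(nz - 1, (int)std::floor(cz + rv));
    for (int k = z0; k <= z1; ++k) {
      const double dz = (k - cz) * voxel, dz2 = dz * dz;
      for (int j = y0; j <= y1; ++j) {
        const double dy = (j - cy) * voxel, d2yz = dz2 + dy * dy;
        if (d2yz > r2) continue;
        for (int i = x0; i <= x1; ++i) {
          const double dx = (i - cx) * voxel;
          if (d2yz + dx * dx <= r2) g[idx3(i, j, k, nx, ny)] = 0.0;
        }
      }
    }
  }
  return out;
}

// Voxel labels from proximity to backbone atoms: within `radius` of any
// backbone atom a voxel takes the class (0 protein / 1 NA) of the nearest
// such atom; everything else is 2.
// [[Rcpp::export]]
IntegerVector cpp_labels_nearest(IntegerVector dim, NumericVector origin,
                                 double voxel, NumericMatrix pcoords,
                                 NumericMatrix ncoords, double radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  IntegerVector lab(n);
  std::fill(lab.begin(), lab.end(), 2);
  std::vector<double> best(n, R_PosInf);
  const double r2 = radius * radius;
  for (int cls = 0; cls < 2; ++cls) {
    const NumericMatrix &cc = (cls == 0) ? pcoords : ncoords;
    for (int a = 0; a < cc.nrow(); ++a) {
      const double cx = (cc(a, 0) - origin[0]) / voxel;
      const double cy = (cc(a, 1) - origin[1]) / voxel;
      const double cz = (cc(a, 2) - origin[2]) / voxel;
      const double rv = radius / voxel;
      const int x0 = std::max(0, (int)std::ceil(cx - rv)),
                x1 = std::min(nx - 1, (int)std::floor(cx + rv));
      const int y0 = std::max(0, (int)std::ceil(cy - rv)),
                y1 = std::min(ny - 1, (int)std::floor(cy + rv));
      const int z0 = std::max(0, (int)std::ceil(cz - rv)),
                z1 = std::min(nz - 1, (int)std::floor(cz + rv));
      for (int k = z0; k <= z1; ++k) {
        const double dz = (k - cz) * voxel, dz2 = dz * dz;
        for (int j = y0; j <= y1; ++j) {
          const double dy = (j - cy) * voxel, d2yz = dz2 + dy * dy;
          if (d2yz > r2) continue;
          for (int i = x0; i <= x1; ++i) {
            const double dx = (i - cx) * voxel;
            const double d2 = d2yz + dx * dx;
            if (d2 > r2) continue;
            const long v = idx3(i, j, k, nx, ny);
            if (d2 < best[v]) { best[v] = d2; lab[v] = cls; }
          }
        }
      }
    }
  }
  return lab;
}

// Count inter-unit heavy-atom pairs closer than `cutoff` using a cell list
// (cell edge = cutoff), so cost is near-linear in atom count.
// [[Rcpp::export]]
double cpp_clash_pairs(NumericMatrix coords, IntegerVector unit,
                       double cutoff) {
  const int n = coords.nrow();
  if (n == 0) return 0.0;
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int a = 0; a < n; ++a)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], coords(a, d));
      hi[d] = std::max(hi[d], coords(a, d));
    }
  const double cell = cutoff;
  int nc[3];
  for (int d = 0; d < 3; ++d)
    nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);
  std::vector<std::vector<int>> cells((long)nc[0] * nc[1] * nc[2]);
  std::vector<int> ci(n), cj(n), ck(n);
  for (int a = 0; a < n; ++a) {
    ci[a] = std::min(nc[0] - 1, (int)((coords(a, 0) - lo[0]) / cell));
    cj[a] = std::min(nc[1] - 1, (int)((coords(a, 1) - lo[1]) / cell));
    ck[a] = std::min(nc[2] - 1, (int)((coords(a, 2) - lo[2]) / cell));
    cells[idx3(ci[a], cj[a], ck[a], nc[0], nc[1])].push_back(a);
  }
  const double c2 = cutoff * cutoff;
  double count = 0.0;
  for (int a = 0; a < n; ++a) {
    for (int dz = -1; dz <= 1; ++dz) {
      const int z = ck[a] + dz;
      if (z < 0 || z >= nc[2]) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        const int y = cj[a] + dy;
        if (y < 0 || y >= nc[1]) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          const int x = ci[a] + dx;
          if (x < 0 || x >= nc[0]) continue;
          for (int b : cells[idx3(x, y, z, nc[0], nc[1])]) {
            if (b <= a || unit[b] == unit[a]) continue;
            const double ddx = coords(a, 0) - coords(b, 0);
            const double ddy = coords(a, 1) - coords(b, 1);
            const double ddz = coords(a, 2) - coords(b, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz < c2) count += 1.0;
          }
        }
      }
    }
  }
  return count;
}

// Separable Gaussian smoothing (sigma in voxels), truncated at 3 sigma.
// [[Rcpp::export]]
NumericVector cpp_smooth_gaussian(NumericVector grid, IntegerVector dim,
                                  double sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int r = std::max(1, (int)std::ceil(3.0 * sigma_vox));
  std::vector<double> w(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    w[i + r] = std::exp(-0.5 * i * i / (sigma_vox * sigma_vox));
    s += w[i + r];
  }
  for (double &x : w) x /= s;
  NumericVector a = clone(grid), b((long)nx * ny * nz);
  double *pa = REAL(a), *pb = REAL(b);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double v = 0.0;
        for (int d = -r; d <= r; ++d) {
          const int x = i + d;
          if (x >= 0 && x < nx) v += w[d + r] * pa[idx3(x, j, k, nx, ny)];
        }
        pb[idx3(i, j, k, nx, ny)] = v;
      }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double v = 0.0;
        for (int d = -r; d <= r; ++d) {
          const int y = j + d;
          if (y >= 0 && y < ny) v += w[d + r] * pb[idx3(i, y, k, nx, ny)];
        }
        pa[idx3(i, j, k, nx, ny)] = v;
      }
  // z pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double v = 0.0;
        for (int d = -r; d <= r; ++d) {
          const int z = k + d;
          if (z >= 0 && z < nz) v += w[d + r] * pa[idx3(i, j, z, nx, ny)];
        }
        pb[idx3(i, j, k, nx, ny)] = v;
      }
  return b;
}

// Local maxima (strictly greater than all 26 neighbours, positive value),
// greedily thinned to a minimum separation; returns up to n_max rows of
// (ix, iy, iz, value), 0-based indices, ordered by decreasing value.
// [[Rcpp::export]]
NumericMatrix cpp_local_maxima(NumericVector grid, IntegerVector dim,
                               double min_sep_vox, int n_max) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *g = REAL(grid);
  std::vector<std::array<double, 4>> peaks;
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        const double v = g[idx3(i, j, k, nx, ny)];
        if (v <= 0) continue;
        bool is_max = true;
        for (int dz = -1; dz <= 1 && is_max; ++dz)
          for (int dy = -1; dy <= 1 && is_max; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              if (g[idx3(i + dx, j + dy, k + dz, nx, ny)] >= v) {
                is_max = false;
                break;
              }
            }
        if (is_max) peaks.push_back({(double)i, (double)j, (double)k, v});
      }
  std::sort(peaks.begin(), peaks.end(),
            [](const std::array<double, 4> &a, const std::array<double, 4> &b) {
              return a[3] > b[3];
            });
  std::vector<std::array<double, 4>> kept;
  const double sep2 = min_sep_vox * min_sep_vox;
  for (auto &p : peaks) {
    bool ok = true;
    for (auto &q : kept) {
      const double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
      if (dx * dx + dy * dy + dz * dz < sep2) { ok = false; break; }
    }
    if (ok) {
      kept.push_back(p);
      if ((int)kept.size() >= n_max) break;
    }
  }
  NumericMatrix out(kept.size(), 4);
  for (size_t r = 0; r < kept.size(); ++r)
    for (int c = 0; c < 4; ++c) out(r, c) = kept[r][c];
  return out;
}
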