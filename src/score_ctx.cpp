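// Pose-scoring context. Built once per (chain, map) pair, then evaluated
// thousands of times inside the rigid-body optimizer, so everything that
// does not depend on the pose (experimental-map support statistics, the
// Fourier transform of the coarse experimental map, shell lookup tables,
// per-atom metadata, scratch buffers) is precomputed here. One evaluation:
//   1. simulate chain density on the map lattice inside a local bounding
//      box around the chain (contiguous scratch, cache friendly),
//   2. Pearson CC over the union of simulated and experimental support,
//   3. local CC over nine-residue sliding windows (voxels within a fixed
//      radius of the window atoms),
//   4. FSC between simulated and experimental density on a fixed 32^3
//      coarse lattice, integrated over a frequency band (trapezoid),
//   5. composite = normalized weighted sum of the three terms.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <complex>
#include <vector>
#include <cmath>
#include <climits>
using namespace Rcpp;

typedef std::complex<double> cplx;

static inline long idx3(int ix, int iy, int iz, int nx, int ny) {
  return (long)ix + (long)nx * ((long)iy + (long)ny * (long)iz);
}

// In-place iterative radix-2 FFT over a strided line, with precomputed
// twiddle factors (tw[len/2 .. len-1] = exp(-2 pi i j / len)).
static void fft1_strided(cplx *a, int n, long stride, const cplx *tw) {
  for (int i = 1, j = 0; i < n; ++i) {
    int bit = n >> 1;
    for (; j & bit; bit >>= 1) j ^= bit;
    j ^= bit;
    if (i < j) std::swap(a[(long)i * stride], a[(long)j * stride]);
  }
  for (int len = 2; len <= n; len <<= 1) {
    const cplx *w = tw + len / 2;
    for (int i = 0; i < n; i += len) {
      for (int j = 0; j < len / 2; ++j) {
        cplx &lo = a[(long)(i + j) * stride];
        cplx &hi = a[(long)(i + j + len / 2) * stride];
        const cplx v = hi * w[j];
        hi = lo - v;
        lo += v;
      }
    }
  }
}

// 3-D FFT of an n^3 cube in place (x fastest).
static void fft3(std::vector<cplx> &a, int n, const std::vector<cplx> &tw) {
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      fft1_strided(&a[idx3(0, j, k, n, n)], n, 1, tw.data());
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < n; ++i)
      fft1_strided(&a[idx3(i, 0, k, n, n)], n, n, tw.data());
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      fft1_strided(&a[idx3(i, j, 0, n, n)], n, (long)n * n, tw.data());
}

static std::vector<cplx> make_twiddles(int n) {
  // tw[len/2 + j] = exp(-2 pi i j / len) for each stage length
  std::vector<cplx> tw(n, cplx(1, 0));
  for (int len = 2; len <= n; len <<= 1)
    for (int j = 0; j < len / 2; ++j) {
      const double ang = -2.0 * M_PI * j / len;
      tw[len / 2 + j] = cplx(std::cos(ang), std::sin(ang));
    }
  return tw;
}

struct ScoreCtx {
  // map lattice
  int nx, ny, nz;
  double voxel, ox, oy, oz;
  std::vector<double> exp_map;   // experimental density
  std::vector<uint8_t> sup;      // exp > support_eps
  double Se, See;                // sums over exp support
  long Ne;
  double support_eps;
  // atoms
  int natom, nres;
  std::vector<double> amp;
  std::vector<int> res_atom_start, res_atom_end; // [start,end) atom ranges
  // kernel
  double sigma, cutoff_sigma;
  // local CC
  double loc_radius;
  int frag_half;
  std::vector<std::array<int, 3>> sphere_off;  // voxel offsets, |d| <= loc_radius
  // coarse FSC lattice (cn^3 cube, voxel cvox, origin co*)
  int cn;
  double cvox, cox, coy, coz;
  std::vector<cplx> Fexp, tw;
  std::vector<int> shell;        // shell index per coarse voxel (-1 = beyond)
  int nshell, band_lo, band_hi;
  std::vector<double> Pexp;      // sum |Fexp|^2 per shell
  // scratch (local box)
  std::vector<double> lsim;
  std::vector<int> lstamp;
  int lstampcur;
  std::vector<double> csim;
  std::vector<cplx> Fsim;
};

static void ctx_finalizer(ScoreCtx *p) { delete p; }
typedef XPtr<ScoreCtx, PreserveStorage, ctx_finalizer> CtxPtr;

// [[Rcpp::export]]
SEXP cpp_score_ctx(NumericVector exp_grid, IntegerVector dim,
                   NumericVector origin, double voxel, double resolution,
                   NumericVector amp, IntegerVector res_of_atom,
                   double loc_radius, int frag_half, double cutoff_sigma,
                   int coarse_n, double fsc_band_lo, double fsc_band_hi,
                   double support_eps) {
  ScoreCtx *c = new ScoreCtx();
  c->nx = dim[0]; c->ny = dim[1]; c->nz = dim[2];
  c->voxel = voxel; c->ox = origin[0]; c->oy = origin[1]; c->oz = origin[2];
  const long n = (long)c->nx * c->ny * c->nz;
  c->exp_map.assign(REAL(exp_grid), REAL(exp_grid) + n);
  c->support_eps = support_eps;
  c->sup.assign(n, 0);
  c->Se = 0.0; c->See = 0.0; c->Ne = 0;
  for (long v = 0; v < n; ++v)
    if (c->exp_map[v] > support_eps) {
      c->sup[v] = 1;
      c->Se += c->exp_map[v];
      c->See += c->exp_map[v] * c->exp_map[v];
      ++c->Ne;
    }
  c->natom = amp.size();
  c->amp.assign(amp.begin(), amp.end());
  c->nres = 0;
  for (int a = 0; a < c->natom; ++a)
    c->nres = std::max(c->nres, res_of_atom[a] + 1);
  // atoms are required grouped by residue in increasing index order
  c->res_atom_start.assign(c->nres, 0);
  c->res_atom_end.assign(c->nres, 0);
  for (int a = 0; a < c->natom; ++a) {
    const int r = res_of_atom[a];
    if (c->res_atom_end[r] == 0) c->res_atom_start[r] = a;
    c->res_atom_end[r] = a + 1;
  }
  c->sigma = resolution / (M_PI * std::sqrt(2.0));
  c->cutoff_sigma = cutoff_sigma;
  c->loc_radius = loc_radius;
  c->frag_half = frag_half;
  // sphere offsets for the local-CC support (voxel units)
  const int lrv = (int)std::floor(loc_radius / voxel);
  for (int dz = -lrv; dz <= lrv; ++dz)
    for (int dy = -lrv; dy <= lrv; ++dy)
      for (int dx = -lrv; dx <= lrv; ++dx)
        if ((dx * dx + dy * dy + dz * dz) * voxel * voxel <=
            loc_radius * loc_radius)
          c->sphere_off.push_back({dx, dy, dz});
  // coarse lattice: cube of side coarse_n covering the map extent
  c->cn = coarse_n;
  const double extx = c->nx * voxel, exty = c->ny * voxel, extz = c->nz * voxel;
  const double side = std::max(extx, std::max(exty, extz));
  c->cvox = side / coarse_n;
  c->cox = c->ox + 0.5 * (extx - side);
  c->coy = c->oy + 0.5 * (exty - side);
  c->coz = c->oz + 0.5 * (extz - side);
  c->tw = make_twiddles(coarse_n);
  const long cn3 = (long)coarse_n * coarse_n * coarse_n;
  // resample experimental map onto the coarse cube (trilinear)
  c->Fexp.assign(cn3, cplx(0, 0));
  for (int k = 0; k < coarse_n; ++k)
    for (int j = 0; j < coarse_n; ++j)
      for (int i = 0; i < coarse_n; ++i) {
        const double px = (c->cox + i * c->cvox - c->ox) / voxel;
        const double py = (c->coy + j * c->cvox - c->oy) / voxel;
        const double pz = (c->coz + k * c->cvox - c->oz) / voxel;
        const int ix = (int)std::floor(px), iy = (int)std::floor(py),
                  iz = (int)std::floor(pz);
        const double fx = px - ix, fy = py - iy, fz = pz - iz;
        double v = 0.0;
        for (int dz = 0; dz <= 1; ++dz) {
          const int z = iz + dz;
          if (z < 0 || z >= c->nz) continue;
          for (int dy = 0; dy <= 1; ++dy) {
            const int y = iy + dy;
            if (y < 0 || y >= c->ny) continue;
            for (int dx = 0; dx <= 1; ++dx) {
              const int x = ix + dx;
              if (x < 0 || x >= c->nx) continue;
              v += (dz ? fz : 1 - fz) * (dy ? fy : 1 - fy) *
                   (dx ? fx : 1 - fx) * c->exp_map[idx3(x, y, z, c->nx, c->ny)];
            }
          }
        }
        c->Fexp[idx3(i, j, k, coarse_n, coarse_n)] = cplx(v, 0.0);
      }
  fft3(c->Fexp, coarse_n, c->tw);
  // shell index per voxel: integer radius in frequency-voxel units
  c->nshell = coarse_n / 2 + 1;
  c->shell.assign(cn3, -1);
  c->Pexp.assign(c->nshell, 0.0);
  for (int k = 0; k < coarse_n; ++k) {
    const int fk = (k <= coarse_n / 2) ? k : k - coarse_n;
    for (int j = 0; j < coarse_n; ++j) {
      const int fj = (j <= coarse_n / 2) ? j : j - coarse_n;
      for (int i = 0; i < coarse_n; ++i) {
        const int fi = (i <= coarse_n / 2) ? i : i - coarse_n;
        const int s = (int)std::floor(
            std::sqrt((double)(fi * fi + fj * fj + fk * fk)) + 0.5);
        if (s < c->nshell) {
          const long v = idx3(i, j, k, coarse_n, coarse_n);
          c->shell[v] = s;
          c->Pexp[s] += std::norm(c->Fexp[v]);
        }
      }
    }
  }
  // frequency of shell s = s / (coarse_n * cvox)  [1/A]
  const double df = 1.0 / (coarse_n * c->cvox);
  int lo = (int)std::ceil(fsc_band_lo / df),
      hi = (int)std::floor(fsc_band_hi / df);
  lo = std::max(lo, 1);
  hi = std::min(hi, c->nshell - 1);
  if (hi < lo) { lo = 1; hi = c->nshell - 1; }
  c->band_lo = lo; c->band_hi = hi;
  c->lstampcur = 0;
  c->csim.assign(cn3, 0.0);
  c->Fsim.assign(cn3, cplx(0, 0));
  CtxPtr p(c, true);
  return p;
}

static double pearson_from_sums(double n, double sx, double sxx, double sy,
                                double syy, double sxy) {
  const double vx = n * sxx - sx * sx, vy = n * syy - sy * sy;
  if (vx <= 0.0 || vy <= 0.0) return 0.0;
  return (n * sxy - sx * sy) / std::sqrt(vx * vy);
}

// Evaluate the composite score for one placement of the chain.
// weights: (global CC, mean local CC, iFSC); loc_stride subsamples the
// sliding windows during optimization (1 = every residue).
// [[Rcpp::export]]
List cpp_score_eval(SEXP ctxp, NumericMatrix coords, NumericVector weights,
                    int loc_stride, bool per_residue) {
  CtxPtr p(ctxp);
  ScoreCtx *c = p.get();
  const int nx = c->nx, ny = c->ny, nz = c->nz;
  const bool do_loc = (weights[1] != 0.0) || per_residue;
  const bool do_fsc = (weights[2] != 0.0);
  const double rcut = c->cutoff_sigma * c->sigma;
  const double inv2s2 = 1.0 / (2.0 * c->sigma * c->sigma);
  // --- local bounding box around the chain ---
  double blo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double bhi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int a = 0; a < c->natom; ++a)
    for (int d = 0; d < 3; ++d) {
      blo[d] = std::min(blo[d], coords(a, d));
      bhi[d] = std::max(bhi[d], coords(a, d));
    }
  const double margin = std::max(rcut, c->loc_radius) + c->voxel;
  const double org[3] = {c->ox, c->oy, c->oz};
  int l0[3], l1[3];
  const int ndim[3] = {nx, ny, nz};
  for (int d = 0; d < 3; ++d) {
    l0[d] = std::max(0, (int)std::floor((blo[d] - margin - org[d]) / c->voxel));
    l1[d] = std::min(ndim[d] - 1,
                     (int)std::ceil((bhi[d] + margin - org[d]) / c->voxel));
    if (l1[d] < l0[d]) { l0[d] = 0; l1[d] = -1; }
  }
  const int lx = l1[0] - l0[0] + 1, ly = l1[1] - l0[1] + 1,
            lz = l1[2] - l0[2] + 1;
  const long ln = std::max(0L, (long)lx * ly * lz);
  if ((long)c->lsim.size() < ln) {
    c->lsim.assign(ln, 0.0);
    c->lstamp.assign(ln, 0);
    c->lstampcur = 0;
  } else {
    std::fill(c->lsim.begin(), c->lsim.begin() + ln, 0.0);
  }
  // --- 1. simulate density inside the local box ---
  std::vector<double> wx, wy, wz;
  for (int a = 0; a < c->natom; ++a) {
    const double cx = (coords(a, 0) - org[0]) / c->voxel - l0[0];
    const double cy = (coords(a, 1) - org[1]) / c->voxel - l0[1];
    const double cz = (coords(a, 2) - org[2]) / c->voxel - l0[2];
    const double rv = rcut / c->voxel;
    const int x0 = std::max(0, (int)std::ceil(cx - rv)),
              x1 = std::min(lx - 1, (int)std::floor(cx + rv));
    const int y0 = std::max(0, (int)std::ceil(cy - rv)),
              y1 = std::min(ly - 1, (int)std::floor(cy + rv));
    const int z0 = std::max(0, (int)std::ceil(cz - rv)),
              z1 = std::min(lz - 1, (int)std::floor(cz + rv));
    if (x0 > x1 || y0 > y1 || z0 > z1) continue;
    wx.resize(x1 - x0 + 1); wy.resize(y1 - y0 + 1); wz.resize(z1 - z0 + 1);
    for (int i = x0; i <= x1; ++i) {
      const double d = (i - cx) * c->voxel;
      wx[i - x0] = std::exp(-d * d * inv2s2);
    }
    for (int j = y0; j <= y1; ++j) {
      const double d = (j - cy) * c->voxel;
      wy[j - y0] = std::exp(-d * d * inv2s2);
    }
    for (int k = z0; k <= z1; ++k) {
      const double d = (k - cz) * c->voxel;
      wz[k - z0] = std::exp(-d * d * inv2s2);
    }
    const double A = c->amp[a];
    for (int k = z0; k <= z1; ++k) {
      const double Az = A * wz[k - z0];
      for (int j = y0; j <= y1; ++j) {
        const double Azy = Az * wy[j - y0];
        double *row = &c->lsim[idx3(x0, j, k, lx, ly)];
        for (int i = 0; i <= x1 - x0; ++i) row[i] += Azy * wx[i];
      }
    }
  }
  // --- 2. global CC over the support union ---
  double Ss = 0.0, Sss = 0.0, Ses = 0.0, extraSe = 0.0, extraSee = 0.0;
  long n_extra = 0;
  for (int k = 0; k < lz; ++k)
    for (int j = 0; j < ly; ++j) {
      const double *srow = &c->lsim[idx3(0, j, k, lx, ly)];
      const double *erow = &c->exp_map[idx3(l0[0], j + l0[1], k + l0[2], nx, ny)];
      const uint8_t *urow = &c->sup[idx3(l0[0], j + l0[1], k + l0[2], nx, ny)];
      for (int i = 0; i < lx; ++i) {
        const double s = srow[i];
        if (s <= c->support_eps) continue;
        const double e = erow[i];
        Ss += s; Sss += s * s; Ses += e * s;
        if (!urow[i]) { ++n_extra; extraSe += e; extraSee += e * e; }
      }
    }
  const double nU = (double)(c->Ne + n_extra);
  double gcc = 0.0;
  if (nU > 1)
    gcc = pearson_from_sums(nU, c->Se + extraSe, c->See + extraSee, Ss, Sss,
                            Ses);
  // --- 3. local CC over sliding nine-residue windows ---
  double mlcc = 0.0;
  NumericVector rescc;
  if (per_residue) rescc = NumericVector(c->nres);
  if (do_loc && ln > 0) {
    int nwin = 0;
    for (int r = 0; r < c->nres; r += (per_residue ? 1 : loc_stride)) {
      const int rlo = std::max(0, r - c->frag_half);
      const int rhi = std::min(c->nres - 1, r + c->frag_half);
      if (++c->lstampcur == INT_MAX) {
        std::fill(c->lstamp.begin(), c->lstamp.end(), 0);
        c->lstampcur = 1;
      }
      double sx = 0, sxx = 0, sy = 0, syy = 0, sxy = 0;
      long nv = 0;
      for (int rr = rlo; rr <= rhi; ++rr) {
        for (int a = c->res_atom_start[rr]; a < c->res_atom_end[rr]; ++a) {
          const int ax = (int)std::round((coords(a, 0) - org[0]) / c->voxel) -
                         l0[0];
          const int ay = (int)std::round((coords(a, 1) - org[1]) / c->voxel) -
                         l0[1];
          const int az = (int)std::round((coords(a, 2) - org[2]) / c->voxel) -
                         l0[2];
          for (const auto &off : c->sphere_off) {
            const int i = ax + off[0], j = ay + off[1], k = az + off[2];
            if (i < 0 || i >= lx || j < 0 || j >= ly || k < 0 || k >= lz)
              continue;
            const long v = idx3(i, j, k, lx, ly);
            if (c->lstamp[v] == c->lstampcur) continue;
            c->lstamp[v] = c->lstampcur;
            const double s = c->lsim[v];
            const double e =
                c->exp_map[idx3(i + l0[0], j + l0[1], k + l0[2], nx, ny)];
            sx += e; sxx += e * e; sy += s; syy += s * s; sxy += e * s;
            ++nv;
          }
        }
      }
      const double cc =
          (nv > 1) ? pearson_from_sums((double)nv, sx, sxx, sy, syy, sxy) : 0.0;
      if (per_residue) rescc[r] = cc;
      mlcc += cc;
      ++nwin;
    }
    if (nwin > 0) mlcc /= nwin;
  }
  // --- 4. integrated FSC on the coarse lattice ---
  double ifsc = 0.0;
  if (do_fsc) {
    const int cn = c->cn;
    const long cn3 = (long)cn * cn * cn;
    std::fill(c->csim.begin(), c->csim.end(), 0.0);
    const double rvc = rcut / c->cvox;
    for (int a = 0; a < c->natom; ++a) {
      const double cx = (coords(a, 0) - c->cox) / c->cvox;
      const double cy = (coords(a, 1) - c->coy) / c->cvox;
      const double cz = (coords(a, 2) - c->coz) / c->cvox;
      const int x0 = std::max(0, (int)std::ceil(cx - rvc)),
                x1 = std::min(cn - 1, (int)std::floor(cx + rvc));
      const int y0 = std::max(0, (int)std::ceil(cy - rvc)),
                y1 = std::min(cn - 1, (int)std::floor(cy + rvc));
      const int z0 = std::max(0, (int)std::ceil(cz - rvc)),
                z1 = std::min(cn - 1, (int)std::floor(cz + rvc));
      if (x0 > x1 || y0 > y1 || z0 > z1) continue;
      wx.resize(x1 - x0 + 1); wy.resize(y1 - y0 + 1); wz.resize(z1 - z0 + 1);
      for (int i = x0; i <= x1; ++i) {
        const double d = (i - cx) * c->cvox;
        wx[i - x0] = std::exp(-d * d * inv2s2);
      }
      for (int j = y0; j <= y1; ++j) {
        const double d = (j - cy) * c->cvox;
        wy[j - y0] = std::exp(-d * d * inv2s2);
      }
      for (int k = z0; k <= z1; ++k) {
        const double d = (k - cz) * c->cvox;
        wz[k - z0] = std::exp(-d * d * inv2s2);
      }
      const double A = c->amp[a];
      for (int k = z0; k <= z1; ++k) {
        const double Az = A * wz[k - z0];
        for (int j = y0; j <= y1; ++j) {
          const double Azy = Az * wy[j - y0];
          double *row = &c->csim[idx3(x0, j, k, cn, cn)];
          for (int i = 0; i <= x1 - x0; ++i) row[i] += Azy * wx[i];
        }
      }
    }
    for (long v = 0; v < cn3; ++v) c->Fsim[v] = cplx(c->csim[v], 0.0);
    fft3(c->Fsim, cn, c->tw);
    std::vector<double> num(c->nshell, 0.0), psim(c->nshell, 0.0);
    for (long v = 0; v < cn3; ++v) {
      const int s = c->shell[v];
      if (s < 0) continue;
      num[s] += std::real(c->Fsim[v] * std::conj(c->Fexp[v]));
      psim[s] += std::norm(c->Fsim[v]);
    }
    double tot = 0.0, wsum = 0.0;
    for (int s = c->band_lo; s <= c->band_hi; ++s) {
      const double den = std::sqrt(psim[s] * c->Pexp[s]);
      const double f = (den > 0.0) ? num[s] / den : 0.0;
      const double w =
          (s == c->band_lo || s == c->band_hi) && c->band_hi > c->band_lo
              ? 0.5 : 1.0;
      tot += w * f;
      wsum += w;
    }
    ifsc = (wsum > 0.0) ? tot / wsum : 0.0;
  }
  const double wsum = weights[0] + weights[1] + weights[2];
  const double comp =
      (wsum > 0)
          ? (weights[0] * gcc + weights[1] * mlcc + weights[2] * ifsc) / wsum
          : 0.0;
  List out = List::create(_["composite"] = comp, _["global_cc"] = gcc,
                          _["mean_local_cc"] = mlcc, _["ifsc"] = ifsc);
  if (per_residue) out["per_residue_cc"] = rescc;
  return out;
}
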