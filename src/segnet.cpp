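// Compact 3-D nested encoder-decoder for voxel classification
// (protein / NA / background), written directly against BLAS via Armadillo
// so that desk-scale training is practical on one CPU core. Feature maps are
// (channels x voxels) float matrices, voxels x-fastest in a cubic lattice.
//
// Topology (three levels, base width w), for a 64^3 chunk:
//   enc1: 3^3 conv stride 2, 1 -> w        64^3 -> 32^3
//   enc2: 3^3 conv stride 2, w -> 2w       32^3 -> 16^3
//   mid : 3^3 conv stride 1, 2w -> w       16^3
//   dec : 1^3 conv over [enc1 ; up2(mid)]  -> w at 32^3
//   head: 1^3 conv over [input ; up2(dec) ; up4(mid)] -> 3 classes at 64^3
//
// The decoder and head are 1x1 convolutions over dense multi-scale skip
// concatenations; because a 1x1 convolution commutes with nearest-neighbour
// upsampling, each block is applied at its native resolution and only the
// 3-channel logits are ever assembled on the full lattice. The stored
// parameterization is identical to the concatenated form.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

static inline long vidx(int i, int j, int k, int n) {
  return (long)i + (long)n * ((long)j + (long)n * (long)k);
}

// im2col for a 3^3 kernel, zero padding 1, stride s, on an n^3 cube.
// Input X: (Cin, n^3); output: (27*Cin, m^3) with m = n/s.
static fmat im2col3(const fmat &X, int n, int s) {
  const int cin = X.n_rows;
  const int m = n / s;
  fmat col(27 * cin, (long)m * m * m, arma::fill::zeros);
  for (int k = 0; k < m; ++k) {
    for (int j = 0; j < m; ++j) {
      for (int i = 0; i < m; ++i) {
        float *dst = col.colptr(vidx(i, j, k, m));
        int off = 0;
        for (int dz = -1; dz <= 1; ++dz) {
          const int z = k * s + dz;
          for (int dy = -1; dy <= 1; ++dy) {
            const int y = j * s + dy;
            for (int dx = -1; dx <= 1; ++dx) {
              const int x = i * s + dx;
              if (x >= 0 && x < n && y >= 0 && y < n && z >= 0 && z < n) {
                const float *src = X.colptr(vidx(x, y, z, n));
                std::copy(src, src + cin, dst + off);
              }
              off += cin;
            }
          }
        }
      }
    }
  }
  return col;
}

// Transpose of im2col3: scatter-add column gradients back onto the input.
static fmat col2im3(const fmat &dcol, int cin, int n, int s) {
  const int m = n / s;
  fmat dX(cin, (long)n * n * n, arma::fill::zeros);
  for (int k = 0; k < m; ++k) {
    for (int j = 0; j < m; ++j) {
      for (int i = 0; i < m; ++i) {
        const float *src = dcol.colptr(vidx(i, j, k, m));
        int off = 0;
        for (int dz = -1; dz <= 1; ++dz) {
          const int z = k * s + dz;
          for (int dy = -1; dy <= 1; ++dy) {
            const int y = j * s + dy;
            for (int dx = -1; dx <= 1; ++dx) {
              const int x = i * s + dx;
              if (x >= 0 && x < n && y >= 0 && y < n && z >= 0 && z < n) {
                float *dst = dX.colptr(vidx(x, y, z, n));
                for (int c = 0; c < cin; ++c) dst[c] += src[off + c];
              }
              off += cin;
            }
          }
        }
      }
    }
  }
  return dX;
}

// Nearest-neighbour upsampling by factor f (cube side m -> f*m), and its
// transpose (sum over the f^3 children).
static fmat upsample(const fmat &X, int m, int f) {
  const int n = m * f;
  const int C = X.n_rows;
  fmat Y(C, (long)n * n * n);
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j) {
      const long srow = (long)m * ((long)(j / f) + (long)m * (k / f));
      float *dst = Y.colptr(vidx(0, j, k, n));
      for (int i = 0; i < n; ++i) {
        const float *src = X.colptr(srow + i / f);
        std::copy(src, src + C, dst + (long)i * C);
      }
    }
  return Y;
}

static fmat upsample_back(const fmat &dY, int m, int f) {
  const int n = m * f;
  const int C = dY.n_rows;
  fmat dX(C, (long)m * m * m, arma::fill::zeros);
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j) {
      const long srow = (long)m * ((long)(j / f) + (long)m * (k / f));
      const float *src = dY.colptr(vidx(0, j, k, n));
      for (int i = 0; i < n; ++i) {
        float *dst = dX.colptr(srow + i / f);
        for (int c = 0; c < C; ++c) dst[c] += src[(long)i * C + c];
      }
    }
  return dX;
}

static inline void relu_(fmat &x) {
  float *p = x.memptr();
  const long n = x.n_elem;
  for (long i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = 0;
}

// gradient masked by activation: g <- g * (a > 0)
static inline void relu_mask_(fmat &g, const fmat &a) {
  float *pg = g.memptr();
  const float *pa = a.memptr();
  const long n = g.n_elem;
  for (long i = 0; i < n; ++i)
    if (pa[i] <= 0) pg[i] = 0;
}

struct SegWeights {
  fmat W1, W2, W3, W4a, W4b, W5u, W5v;
  fvec b1, b2, b3, b4, b5, W5x;
};

static SegWeights unpack(const List &W) {
  SegWeights s;
  s.W1 = as<fmat>(W["W1"]); s.b1 = as<fvec>(W["b1"]);
  s.W2 = as<fmat>(W["W2"]); s.b2 = as<fvec>(W["b2"]);
  s.W3 = as<fmat>(W["W3"]); s.b3 = as<fvec>(W["b3"]);
  s.W4a = as<fmat>(W["W4a"]); s.W4b = as<fmat>(W["W4b"]);
  s.b4 = as<fvec>(W["b4"]);
  s.W5x = as<fvec>(W["W5x"]); s.W5u = as<fmat>(W["W5u"]);
  s.W5v = as<fmat>(W["W5v"]); s.b5 = as<fvec>(W["b5"]);
  return s;
}

struct FwdState {
  fmat x0, col1, a1, col2, a2, col3, a3, a4, logits;
};

static void seg_forward_full(const SegWeights &w, const NumericVector &chunk,
                             int n0, FwdState &st, bool keep_cols) {
  const int n1 = n0 / 2, n2 = n0 / 4;
  const long N0 = (long)n0 * n0 * n0;
  st.x0 = fmat(1, N0);
  for (long v = 0; v < N0; ++v) st.x0(0, v) = (float)chunk[v];
  st.col1 = im2col3(st.x0, n0, 2);
  st.a1 = w.W1 * st.col1;
  st.a1.each_col() += w.b1;
  relu_(st.a1);
  st.col2 = im2col3(st.a1, n1, 2);
  st.a2 = w.W2 * st.col2;
  st.a2.each_col() += w.b2;
  relu_(st.a2);
  st.col3 = im2col3(st.a2, n2, 1);
  st.a3 = w.W3 * st.col3;
  st.a3.each_col() += w.b3;
  relu_(st.a3);
  st.a4 = w.W4a * st.a1 + upsample(w.W4b * st.a3, n2, 2);
  st.a4.each_col() += w.b4;
  relu_(st.a4);
  st.logits = w.W5x * st.x0 + upsample(w.W5u * st.a4, n1, 2) +
              upsample(w.W5v * st.a3, n2, 4);
  st.logits.each_col() += w.b5;
  if (!keep_cols) {
    st.col1.reset(); st.col2.reset(); st.col3.reset();
  }
}

// loss + per-voxel softmax grad; labels in {0,1,2}, class-weighted CE
static double ce_loss(const fmat &logits, const IntegerVector &labels,
                      const NumericVector &cw, fmat *dlogits, double *acc) {
  const long n = logits.n_cols;
  double loss = 0.0, wsum = 0.0;
  long correct = 0;
  if (dlogits) dlogits->set_size(3, n);
  for (long v = 0; v < n; ++v) {
    const float l0 = logits(0, v), l1 = logits(1, v), l2 = logits(2, v);
    const float m = std::max(l0, std::max(l1, l2));
    const double e0 = std::exp(l0 - m), e1 = std::exp(l1 - m),
                 e2 = std::exp(l2 - m);
    const double Z = e0 + e1 + e2;
    const double p[3] = {e0 / Z, e1 / Z, e2 / Z};
    const int y = labels[v];
    const double w = cw[y];
    loss += -w * std::log(std::max(p[y], 1e-12));
    wsum += w;
    int pred = 0;
    if (p[1] > p[pred]) pred = 1;
    if (p[2] > p[pred]) pred = 2;
    if (pred == y) ++correct;
    if (dlogits)
      for (int cl = 0; cl < 3; ++cl)
        (*dlogits)(cl, v) = (float)(w * (p[cl] - (cl == y ? 1.0 : 0.0)));
  }
  if (dlogits && wsum > 0) *dlogits /= (float)wsum;
  if (acc) *acc = (double)correct / (double)n;
  return (wsum > 0) ? loss / wsum : 0.0;
}

// One training evaluation: loss, voxel accuracy and gradients for a chunk.
// [[Rcpp::export]]
List cpp_seg_grad(List W, NumericVector chunk, IntegerVector labels,
                  NumericVector class_w, int n0) {
  SegWeights w = unpack(W);
  FwdState st;
  seg_forward_full(w, chunk, n0, st, true);
  const int n1 = n0 / 2, n2 = n0 / 4;
  fmat dlogits;
  double acc = 0.0;
  const double loss = ce_loss(st.logits, labels, class_w, &dlogits, &acc);
  // head
  fvec db5 = arma::sum(dlogits, 1);
  fvec dW5x = dlogits * st.x0.t();
  fmat dls = upsample_back(dlogits, n1, 2);   // (3, N1)
  fmat dlm = upsample_back(dlogits, n2, 4);   // (3, N2)
  fmat dW5u = dls * st.a4.t();
  fmat da4 = w.W5u.t() * dls;
  fmat dW5v = dlm * st.a3.t();
  fmat da3 = w.W5v.t() * dlm;
  // dec
  relu_mask_(da4, st.a4);
  fvec db4 = arma::sum(da4, 1);
  fmat dW4a = da4 * st.a1.t();
  fmat da1 = w.W4a.t() * da4;
  fmat da4s = upsample_back(da4, n2, 2);
  fmat dW4b = da4s * st.a3.t();
  da3 += w.W4b.t() * da4s;
  // mid
  relu_mask_(da3, st.a3);
  fmat dW3 = da3 * st.col3.t();
  fvec db3 = arma::sum(da3, 1);
  fmat da2 = col2im3(w.W3.t() * da3, w.W2.n_rows, n2, 1);
  // enc2
  relu_mask_(da2, st.a2);
  fmat dW2 = da2 * st.col2.t();
  fvec db2 = arma::sum(da2, 1);
  da1 += col2im3(w.W2.t() * da2, w.W1.n_rows, n1, 2);
  // enc1
  relu_mask_(da1, st.a1);
  fmat dW1 = da1 * st.col1.t();
  fvec db1 = arma::sum(da1, 1);
  return List::create(
      _["loss"] = loss, _["acc"] = acc,
      _["grads"] = List::create(
          _["W1"] = dW1, _["b1"] = db1, _["W2"] = dW2, _["b2"] = db2,
          _["W3"] = dW3, _["b3"] = db3, _["W4a"] = dW4a, _["W4b"] = dW4b,
          _["b4"] = db4, _["W5x"] = dW5x, _["W5u"] = dW5u, _["W5v"] = dW5v,
          _["b5"] = db5));
}

// Forward-only loss/accuracy (validation).
// [[Rcpp::export]]
List cpp_seg_eval(List W, NumericVector chunk, IntegerVector labels,
                  NumericVector class_w, int n0) {
  SegWeights w = unpack(W);
  FwdState st;
  seg_forward_full(w, chunk, n0, st, false);
  double acc = 0.0;
  const double loss = ce_loss(st.logits, labels, class_w, NULL, &acc);
  return List::create(_["loss"] = loss, _["acc"] = acc);
}

// Forward pass returning per-voxel class probabilities (3 x n0^3).
// [[Rcpp::export]]
NumericMatrix cpp_seg_forward(List W, NumericVector chunk, int n0) {
  SegWeights w = unpack(W);
  FwdState st;
  seg_forward_full(w, chunk, n0, st, false);
  const long n = st.logits.n_cols;
  NumericMatrix out(3, n);
  for (long v = 0; v < n; ++v) {
    const float l0 = st.logits(0, v), l1 = st.logits(1, v), l2 = st.logits(2, v);
    const float m = std::max(l0, std::max(l1, l2));
    const double e0 = std::exp(l0 - m), e1 = std::exp(l1 - m),
                 e2 = std::exp(l2 - m);
    const double Z = e0 + e1 + e2;
    out(0, v) = e0 / Z;
    out(1, v) = e1 / Z;
    out(2, v) = e2 / Z;
  }
  return out;
}
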