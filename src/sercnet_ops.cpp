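// Convolution and pooling kernels backing the SE-RCNet implementation.
// Layout convention matches R arrays: activations are [H, W, C, N]
// column-major; convolution weights are [k*k*Cin, Cout] with the patch
// dimension ordered (fast-time row offset, column offset, channel) to agree
// with im2col below. 3x3 "same" zero padding, stride 1.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

static void im2col_same(const double* xp, int H, int W, int C, int k, mat& P) {
  const int p = k / 2;
  int col = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (std::size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di, ++col) {
        double* pc = P.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          double* pcj = pc + (std::size_t)j * H;
          if (sj < 0 || sj >= W) { std::fill(pcj, pcj + H, 0.0); continue; }
          const double* xcj = xc + (std::size_t)sj * H;
          const int i0 = std::max(0, p - di), i1 = std::min(H, H + p - di);
          for (int i = 0;  i < i0; ++i) pcj[i] = 0.0;
          for (int i = i0; i < i1; ++i) pcj[i] = xcj[i + di - p];
          for (int i = i1; i < H;  ++i) pcj[i] = 0.0;
        }
      }
    }
  }
}

static void col2im_add(const mat& dP, int H, int W, int C, int k, double* dxp) {
  const int p = k / 2;
  int col = 0;
  for (int c = 0; c < C; ++c) {
    double* xc = dxp + (std::size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di, ++col) {
        const double* pc = dP.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          const double* pcj = pc + (std::size_t)j * H;
          double* xcj = xc + (std::size_t)sj * H;
          const int i0 = std::max(0, p - di), i1 = std::min(H, H + p - di);
          for (int i = i0; i < i1; ++i) xcj[i + di - p] += pcj[i];
        }
      }
    }
  }
}

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector y((R_xlen_t)a * b * c * d);
  y.attr("dim") = IntegerVector::create(a, b, c, d);
  return y;
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d [H,W,C,N] array");
  return d;
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericMatrix Wm,
                            NumericVector b) {
  IntegerVector d = dims4(x);
  const int H = d[0], W_ = d[1], C = d[2], N = d[3];
  const int F = Wm.ncol();
  const int k = (int)std::lround(std::sqrt((double)Wm.nrow() / C));
  if (k * k * C != Wm.nrow()) stop("weight rows must equal k*k*Cin");
  if (b.size() != F) stop("bias length must equal the filter count");
  const mat Wmat(Wm.begin(), Wm.nrow(), F, false);
  const rowvec bv(b.begin(), F, false);
  NumericVector y = alloc4(H, W_, F, N);
  mat P(H * W_, k * k * C);
  const std::size_t xstep = (std::size_t)H * W_ * C;
  const std::size_t ystep = (std::size_t)H * W_ * F;
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + n * xstep, H, W_, C, k, P);
    mat Y(y.begin() + n * ystep, H * W_, F, false, true);
    Y = P * Wmat;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericMatrix Wm, NumericVector dy) {
  IntegerVector d = dims4(x);
  const int H = d[0], W_ = d[1], C = d[2], N = d[3];
  const int F = Wm.ncol();
  const int k = (int)std::lround(std::sqrt((double)Wm.nrow() / C));
  const mat Wmat(Wm.begin(), Wm.nrow(), F, false);
  NumericVector dx = alloc4(H, W_, C, N);
  NumericMatrix dW(Wm.nrow(), F);
  NumericVector db(F);
  mat dWm(dW.begin(), Wm.nrow(), F, false, true);
  vec dbv(db.begin(), F, false, true);
  mat P(H * W_, k * k * C);
  const std::size_t xstep = (std::size_t)H * W_ * C;
  const std::size_t ystep = (std::size_t)H * W_ * F;
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + n * xstep, H, W_, C, k, P);
    const mat dY(const_cast<double*>(dy.begin()) + n * ystep,
                 H * W_, F, false, true);
    dWm += P.t() * dY;
    dbv += sum(dY, 0).t();
    mat dP = dY * Wmat.t();
    col2im_add(dP, H, W_, C, k, dx.begin() + n * xstep);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2, valid windows (trailing odd row/col dropped).
// idx records the 0-based within-sample linear argmax for the backward pass.
// [[Rcpp::export]]
List maxpool2_fw_cpp(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W_ = d[1], C = d[2], N = d[3];
  const int H2 = H / 2, W2 = W_ / 2;
  if (H2 < 1 || W2 < 1) stop("spatial size too small to max-pool");
  NumericVector y = alloc4(H2, W2, C, N);
  IntegerVector idx(y.size());
  const std::size_t xstep = (std::size_t)H * W_ * C;
  std::size_t o = 0;
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + n * xstep;
    for (int c = 0; c < C; ++c) {
      const double* xc = xs + (std::size_t)c * H * W_;
      for (int j = 0; j < W2; ++j) {
        for (int i = 0; i < H2; ++i, ++o) {
          int best = 2 * i + (2 * j) * H;
          double bv = xc[best];
          const int cand[3] = {2 * i + 1 + (2 * j) * H,
                               2 * i + (2 * j + 1) * H,
                               2 * i + 1 + (2 * j + 1) * H};
          for (int q = 0; q < 3; ++q)
            if (xc[cand[q]] > bv) { bv = xc[cand[q]]; best = cand[q]; }
          y[o] = bv;
          idx[o] = best + c * H * W_;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw_cpp(IntegerVector idx, NumericVector dy,
                              int H, int W) {
  IntegerVector d = dims4(dy);
  const int C = d[2], N = d[3];
  NumericVector dx = alloc4(H, W, C, N);
  const std::size_t xstep = (std::size_t)H * W * C;
  const std::size_t ystep = (std::size_t)d[0] * d[1] * C;
  for (int n = 0; n < N; ++n) {
    double* dxs = dx.begin() + n * xstep;
    const std::size_t base = n * ystep;
    for (std::size_t o = 0; o < ystep; ++o)
      dxs[idx[base + o]] += dy[base + o];
  }
  return dx;
}
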