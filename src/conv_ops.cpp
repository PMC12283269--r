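// Hot path of the CNN engine: same-padding 2-D convolution and max pooling
// over batched feature maps. Layout matches the R side: a C-channel H x W
// map for a batch of B samples is a C x (H*W*B) matrix with column index
// (b-1)*H*W + (j-1)*H + i (map stored column-major).

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col_pad(const arma::mat& x, int C, int H, int W, int B,
                            int k) {
  const int pad = (k - 1) / 2;
  const int HW = H * W;
  arma::mat cols(C * k * k, (size_t)HW * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const size_t off = (size_t)b * HW;
    for (int dj = -pad; dj <= pad; ++dj) {
      for (int di = -pad; di <= pad; ++di) {
        const int o = (dj + pad) * k + (di + pad);  // offset row block
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const int i_lo = std::max(0, -di), i_hi = std::min(H, H - di);
          for (int i = i_lo; i < i_hi; ++i) {
            const size_t dst = off + (size_t)j * H + i;
            const size_t src = off + (size_t)js * H + (i + di);
            double* out = cols.colptr(dst) + (size_t)o * C;
            const double* in = x.colptr(src);
            for (int c = 0; c < C; ++c) out[c] = in[c];
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".conv_fwd_cpp")]]
arma::mat conv_fwd_cpp(const arma::mat& x, const arma::mat& Wk,
                       const arma::vec& b, int C, int H, int W, int B,
                       int k, bool relu_out) {
  arma::mat cols = im2col_pad(x, C, H, W, B, k);
  arma::mat y = Wk * cols;
  y.each_col() += b;
  if (relu_out) y.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return y;
}

// [[Rcpp::export(name = ".conv_bwd_cpp")]]
List conv_bwd_cpp(const arma::mat& x, const arma::mat& Wk,
                  const arma::mat& dY, int C, int H, int W, int B, int k,
                  bool need_dx) {
  arma::mat cols = im2col_pad(x, C, H, W, B, k);
  arma::mat dW = dY * cols.t();
  arma::vec db = arma::sum(dY, 1);
  if (!need_dx) {
    return List::create(_["dW"] = dW, _["db"] = db);
  }
  arma::mat dcols = Wk.t() * dY;
  const int pad = (k - 1) / 2;
  const int HW = H * W;
  arma::mat dx(C, (size_t)HW * B, arma::fill::zeros);
  for (int b2 = 0; b2 < B; ++b2) {
    const size_t off = (size_t)b2 * HW;
    for (int dj = -pad; dj <= pad; ++dj) {
      for (int di = -pad; di <= pad; ++di) {
        const int o = (dj + pad) * k + (di + pad);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const int i_lo = std::max(0, -di), i_hi = std::min(H, H - di);
          for (int i = i_lo; i < i_hi; ++i) {
            const size_t dst = off + (size_t)j * H + i;
            const size_t src = off + (size_t)js * H + (i + di);
            double* out = dx.colptr(src);
            const double* in = dcols.colptr(dst) + (size_t)o * C;
            for (int c = 0; c < C; ++c) out[c] += in[c];
          }
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// Elementwise dY * (y > 0): the rectifier's backward pass, done in one
// C-level sweep to avoid R-side logical masks on the large conv maps.
// [[Rcpp::export(name = ".relu_bwd_cpp")]]
arma::mat relu_bwd_cpp(const arma::mat& dY, const arma::mat& y) {
  arma::mat dx(dY.n_rows, dY.n_cols);
  const double* yp = y.memptr();
  const double* dp = dY.memptr();
  double* op = dx.memptr();
  const size_t n = dY.n_elem;
  for (size_t i = 0; i < n; ++i) op[i] = yp[i] > 0.0 ? dp[i] : 0.0;
  return dx;
}

// [[Rcpp::export(name = ".maxpool_fwd_cpp")]]
List maxpool_fwd_cpp(const arma::mat& x, int C, int H, int W, int B, int k) {
  const int Ho = H / k, Wo = W / k;
  const int HW = H * W, HWo = Ho * Wo;
  arma::mat y(C, (size_t)HWo * B);
  IntegerMatrix arg(C, HWo * B);
  for (int b = 0; b < B; ++b) {
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const size_t dst = (size_t)b * HWo + (size_t)jo * Ho + io;
        double* yc = y.colptr(dst);
        int* ac = &arg(0, dst);
        bool first = true;
        for (int dj = 0; dj < k; ++dj) {
          for (int di = 0; di < k; ++di) {
            const int i = io * k + di, j = jo * k + dj;
            const size_t src = (size_t)b * HW + (size_t)j * H + i;
            const double* xc = x.colptr(src);
            const int m = dj * k + di + 1;  // 1-based within-window index
            if (first) {
              for (int c = 0; c < C; ++c) { yc[c] = xc[c]; ac[c] = m; }
              first = false;
            } else {
              for (int c = 0; c < C; ++c) {
                if (xc[c] > yc[c]) { yc[c] = xc[c]; ac[c] = m; }
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd_cpp")]]
arma::mat maxpool_bwd_cpp(const arma::mat& dY, const IntegerMatrix& arg,
                          int C, int H, int W, int B, int k) {
  const int Ho = H / k, Wo = W / k;
  const int HW = H * W, HWo = Ho * Wo;
  arma::mat dx(C, (size_t)HW * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const size_t src = (size_t)b * HWo + (size_t)jo * Ho + io;
        const double* dc = dY.colptr(src);
        const int* ac = &arg(0, src);
        for (int c = 0; c < C; ++c) {
          const int m = ac[c] - 1;
          const int di = m % k, dj = m / k;
          const int i = io * k + di, j = jo * k + dj;
          dx.colptr((size_t)b * HW + (size_t)j * H + i)[c] += dc[c];
        }
      }
    }
  }
  return dx;
}
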