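// Hot loops of the network engine: 3x3 valid convolution forward/backward
// and the batch-normalisation element passes. Activation tensors arrive as
// column-major (H, W, B, C) arrays; kernel weights as a (9*C_in) x C_out
// matrix whose row r = 9*c + j holds input channel c, kernel offset j
// (offset order: dy fastest, i.e. j = dy + 3*dx).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Copy the shifted/strided input slice for kernel offset (dy, dx) into an
// (oh*ow*B) x C matrix, rows ordered (oh, ow, B).
static void fill_slice(const double* x, arma::mat& xs,
                       int h, int w, int B, int C,
                       int oh, int ow, int dy, int dx, int stride) {
  const arma::uword n_spatial = (arma::uword)oh * ow;
  for (int c = 0; c < C; ++c) {
    double* dst = xs.colptr(c);
    for (int b = 0; b < B; ++b) {
      const double* src_plane = x + ((arma::uword)c * B + b) * h * w;
      for (int ox = 0; ox < ow; ++ox) {
        const double* src = src_plane + (arma::uword)(dx + ox * stride) * h + dy;
        double* out = dst + (arma::uword)b * n_spatial + (arma::uword)ox * oh;
        if (stride == 1) {
          std::copy(src, src + oh, out);
        } else {
          for (int oy = 0; oy < oh; ++oy) out[oy] = src[(arma::uword)oy * stride];
        }
      }
    }
  }
}

// Accumulate an (oh*ow*B) x C gradient matrix back into the shifted input
// positions (transpose of fill_slice).
static void scatter_slice(double* dx_out, const arma::mat& dm,
                          int h, int w, int B, int C,
                          int oh, int ow, int dy, int dx, int stride) {
  const arma::uword n_spatial = (arma::uword)oh * ow;
  for (int c = 0; c < C; ++c) {
    const double* src_col = dm.colptr(c);
    for (int b = 0; b < B; ++b) {
      double* dst_plane = dx_out + ((arma::uword)c * B + b) * h * w;
      for (int ox = 0; ox < ow; ++ox) {
        double* dst = dst_plane + (arma::uword)(dx + ox * stride) * h + dy;
        const double* in = src_col + (arma::uword)b * n_spatial + (arma::uword)ox * oh;
        if (stride == 1) {
          for (int oy = 0; oy < oh; ++oy) dst[oy] += in[oy];
        } else {
          for (int oy = 0; oy < oh; ++oy) dst[(arma::uword)oy * stride] += in[oy];
        }
      }
    }
  }
}

static arma::uvec offset_rows(int C, int j) {
  arma::uvec r(C);
  for (int c = 0; c < C; ++c) r[c] = (arma::uword)(9 * c + j);
  return r;
}

// [[Rcpp::export(name = ".conv3_forward")]]
NumericVector conv3_forward(NumericVector x, IntegerVector dims,
                            const arma::mat& wmat, int stride) {
  const int h = dims[0], w = dims[1], B = dims[2], C = dims[3];
  const int oh = (h - 3) / stride + 1, ow = (w - 3) / stride + 1;
  const int cout = wmat.n_cols;
  const arma::uword n_out = (arma::uword)oh * ow * B;
  arma::mat Y(n_out, cout, arma::fill::zeros);
  arma::mat Xs(n_out, C);
  for (int j = 0; j < 9; ++j) {
    fill_slice(REAL(x), Xs, h, w, B, C, oh, ow, j % 3, j / 3, stride);
    Y += Xs * wmat.rows(offset_rows(C, j));
  }
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(oh, ow, B, cout);
  return out;
}

// [[Rcpp::export(name = ".conv3_backward")]]
List conv3_backward(NumericVector dy, NumericVector x, IntegerVector dims,
                    const arma::mat& wmat, int stride) {
  const int h = dims[0], w = dims[1], B = dims[2], C = dims[3];
  const int oh = (h - 3) / stride + 1, ow = (w - 3) / stride + 1;
  const int cout = wmat.n_cols;
  const arma::uword n_out = (arma::uword)oh * ow * B;
  arma::mat dOut(REAL(dy), n_out, cout, false, true);
  arma::mat dW(wmat.n_rows, cout, arma::fill::zeros);
  NumericVector dxv(x.size());
  arma::mat Xs(n_out, C);
  for (int j = 0; j < 9; ++j) {
    const int jy = j % 3, jx = j / 3;
    fill_slice(REAL(x), Xs, h, w, B, C, oh, ow, jy, jx, stride);
    arma::uvec rows = offset_rows(C, j);
    dW.rows(rows) = Xs.t() * dOut;
    arma::mat dM = dOut * wmat.rows(rows).t();
    scatter_slice(REAL(dxv), dM, h, w, B, C, oh, ow, jy, jx, stride);
  }
  dxv.attr("dim") = dims;
  return List::create(_["dX"] = dxv, _["dW"] = wrap(dW));
}

// Element pass of batch normalisation: given per-channel mean and inverse
// standard deviation, produce xhat and the affine output in one sweep.
// m is (n x C) with channels in columns.
// [[Rcpp::export(name = ".bn_apply")]]
List bn_apply(NumericMatrix m, NumericVector mu, NumericVector invstd,
              NumericVector gamma, NumericVector beta) {
  const R_xlen_t n = m.nrow();
  const int C = m.ncol();
  NumericMatrix xhat(n, C), y(n, C);
  for (int c = 0; c < C; ++c) {
    const double mc = mu[c], ic = invstd[c], gc = gamma[c], bc = beta[c];
    const double* src = &m(0, c);
    double* xh = &xhat(0, c);
    double* yy = &y(0, c);
    for (R_xlen_t i = 0; i < n; ++i) {
      const double v = (src[i] - mc) * ic;
      xh[i] = v;
      yy[i] = v * gc + bc;
    }
  }
  return List::create(_["xhat"] = xhat, _["Y"] = y);
}

// Input gradient of batch normalisation (training mode):
// dM = invstd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) per channel,
// where dxhat = gamma * dY.
// [[Rcpp::export(name = ".bn_input_grad")]]
NumericMatrix bn_input_grad(NumericMatrix dym, NumericMatrix xhat,
                            NumericVector invstd, NumericVector gamma,
                            bool training) {
  const R_xlen_t n = dym.nrow();
  const int C = dym.ncol();
  NumericMatrix dM(n, C);
  for (int c = 0; c < C; ++c) {
    const double gc = gamma[c], ic = invstd[c];
    const double* dy = &dym(0, c);
    const double* xh = &xhat(0, c);
    double* out = &dM(0, c);
    if (training) {
      double s1 = 0, s2 = 0;
      for (R_xlen_t i = 0; i < n; ++i) {
        s1 += dy[i];
        s2 += dy[i] * xh[i];
      }
      s1 = gc * s1 / n;
      s2 = gc * s2 / n;
      for (R_xlen_t i = 0; i < n; ++i)
        out[i] = (gc * dy[i] - s1 - xh[i] * s2) * ic;
    } else {
      for (R_xlen_t i = 0; i < n; ++i) out[i] = gc * dy[i] * ic;
    }
  }
  return dM;
}

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double* in = REAL(x);
  double* out = REAL(y);
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = in[i] > 0 ? in[i] : 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  const double* g = REAL(dy);
  const double* v = REAL(y);
  double* out = REAL(dx);
  for (R_xlen_t i = 0; i < dy.size(); ++i) out[i] = v[i] > 0 ? g[i] : 0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// 2x2 max-pooling with argmax bookkeeping. Trailing odd rows/columns are
// dropped. `which` records the winning cell (0 = top-left, 1 = bottom-left,
// 2 = top-right, 3 = bottom-right; ties to the lowest code).
// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, IntegerVector dims) {
  const int h = dims[0], w = dims[1], B = dims[2], C = dims[3];
  const int h2 = h / 2, w2 = w / 2;
  const R_xlen_t n_out = (R_xlen_t)h2 * w2 * B * C;
  NumericVector y(n_out);
  IntegerVector which(n_out);
  const double* in = REAL(x);
  double* out = REAL(y);
  int* wh = INTEGER(which);
  R_xlen_t o = 0;
  for (int q = 0; q < B * C; ++q) {
    const double* plane = in + (R_xlen_t)q * h * w;
    for (int ox = 0; ox < w2; ++ox) {
      const double* col0 = plane + (R_xlen_t)(2 * ox) * h;
      const double* col1 = col0 + h;
      for (int oy = 0; oy < h2; ++oy, ++o) {
        const int r = 2 * oy;
        double best = col0[r];
        int code = 0;
        if (col0[r + 1] > best) { best = col0[r + 1]; code = 1; }
        if (col1[r] > best) { best = col1[r]; code = 2; }
        if (col1[r + 1] > best) { best = col1[r + 1]; code = 3; }
        out[o] = best;
        wh[o] = code;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(h2, w2, B, C);
  return List::create(_["Y"] = y, _["which"] = which);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector which,
                          IntegerVector in_dims) {
  const int h = in_dims[0], w = in_dims[1], B = in_dims[2], C = in_dims[3];
  const int h2 = h / 2, w2 = w / 2;
  NumericVector dx((R_xlen_t)h * w * B * C);
  const double* g = REAL(dy);
  const int* wh = INTEGER(which);
  double* out = REAL(dx);
  R_xlen_t o = 0;
  for (int q = 0; q < B * C; ++q) {
    double* plane = out + (R_xlen_t)q * h * w;
    for (int ox = 0; ox < w2; ++ox) {
      for (int oy = 0; oy < h2; ++oy, ++o) {
        const int code = wh[o];
        const R_xlen_t idx = (R_xlen_t)(2 * ox + (code >> 1)) * h +
          2 * oy + (code & 1);
        plane[idx] += g[o];
      }
    }
  }
  dx.attr("dim") = in_dims;
  return dx;
}
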