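// Low-level layer primitives for the convolutional denoising network.
// Images are arma::cube (rows, cols, channels); convolution weights are a
// matrix with one row per output channel and Cin*k*k columns ordered as
// (channel, kernel col, kernel row) fastest-last, matching im2col below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// "same" zero-padded im2col: output (Cin*k*k) x (H*W), column q = i + j*H
static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  mat cols(C * k * k, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - p;
            if (si < 0 || si >= H) continue;
            cols(r, i + j * H) = xs(si, sj);
          }
        }
      }
    }
  }
  return cols;
}

// adjoint of im2col: scatter-add columns back into an image cube
static cube col2im(const mat& cols, const int H, const int W, const int C,
                   const int k) {
  const int p = (k - 1) / 2;
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& xs = x.slice(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - p;
            if (si < 0 || si >= H) continue;
            xs(si, sj) += cols(r, i + j * H);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, const int k) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Cout = W.n_rows;
  mat cols = im2col(x, k);
  mat y = W * cols;
  y.each_col() += b;
  cube out(H, Wd, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(y.row(c).t(), H, Wd);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& W,
                          const int k, const arma::cube& dy) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  mat cols = im2col(x, k);
  mat dym(Cout, H * Wd);
  for (int c = 0; c < Cout; ++c)
    dym.row(c) = vectorise(dy.slice(c)).t();
  mat dW = dym * cols.t();
  vec db = sum(dym, 1);
  cube dx = col2im(W.t() * dym, H, Wd, Cin, k);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 2x2 stride-2 max pooling; idx records the argmax as a linear index into
// the input slice so the backward pass can scatter gradients exactly.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int si = 2 * i + di, sj = 2 * j + dj;
            if (xs(si, sj) > best) {
              best = xs(si, sj);
              bi = si + sj * H;
            }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const arma::ucube& idx, const arma::cube& dy,
                           const int H, const int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& dxs = dx.slice(c);
    for (uword j = 0; j < dy.n_cols; ++j)
      for (uword i = 0; i < dy.n_rows; ++i)
        dxs(idx(i, j, c)) += dy(i, j, c);
  }
  return dx;
}

// 2x2 stride-2 transposed convolution (learned upsampling). Weight matrix:
// (Cout) x (Cin*4), column index ci*4 + dj*2 + di.
// [[Rcpp::export]]
arma::cube cpp_upconv_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_rows;
  cube y(2 * H, 2 * Wd, Cout);
  for (int co = 0; co < Cout; ++co) y.slice(co).fill(b(co));
  for (int co = 0; co < Cout; ++co) {
    mat& ys = y.slice(co);
    for (int ci = 0; ci < Cin; ++ci) {
      const mat& xs = x.slice(ci);
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const double w = W(co, ci * 4 + dj * 2 + di);
          for (int j = 0; j < Wd; ++j)
            for (int i = 0; i < H; ++i)
              ys(2 * i + di, 2 * j + dj) += w * xs(i, j);
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_upconv_bwd(const arma::cube& x, const arma::mat& W,
                          const arma::cube& dy) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  mat dW(Cout, Cin * 4, fill::zeros);
  vec db(Cout, fill::zeros);
  cube dx(H, Wd, Cin, fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    const mat& dys = dy.slice(co);
    db(co) = accu(dys);
    for (int ci = 0; ci < Cin; ++ci) {
      const mat& xs = x.slice(ci);
      mat& dxs = dx.slice(ci);
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const double w = W(co, ci * 4 + dj * 2 + di);
          double g = 0.0;
          for (int j = 0; j < Wd; ++j)
            for (int i = 0; i < H; ++i) {
              const double d = dys(2 * i + di, 2 * j + dj);
              g += d * xs(i, j);
              dxs(i, j) += w * d;
            }
          dW(co, ci * 4 + dj * 2 + di) = g;
        }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// separable correlation with a symmetric 1D kernel, 'valid' output
// [[Rcpp::export]]
arma::mat cpp_sep_corr_valid(const arma::mat& x, const arma::vec& k) {
  const int H = x.n_rows, W = x.n_cols, n = k.n_elem;
  mat t(H - n + 1, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i + n <= (unsigned)H; ++i) {
      double s = 0.0;
      for (int d = 0; d < n; ++d) s += k(d) * x(i + d, j);
      t(i, j) = s;
    }
  mat y(H - n + 1, W - n + 1);
  for (int j = 0; (unsigned)j + n <= (unsigned)W; ++j)
    for (int i = 0; i < (int)t.n_rows; ++i) {
      double s = 0.0;
      for (int d = 0; d < n; ++d) s += k(d) * t(i, j + d);
      y(i, j) = s;
    }
  return y;
}

// adjoint of the above (full convolution; kernel is symmetric)
// [[Rcpp::export]]
arma::mat cpp_sep_conv_full(const arma::mat& x, const arma::vec& k) {
  const int H = x.n_rows, W = x.n_cols, n = k.n_elem;
  mat t(H + n - 1, W, fill::zeros);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      for (int d = 0; d < n; ++d) t(i + d, j) += k(d) * x(i, j);
  mat y(H + n - 1, W + n - 1, fill::zeros);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < (int)t.n_rows; ++i)
      for (int d = 0; d < n; ++d) y(i, j + d) += k(d) * t(i, j);
  return y;
}
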