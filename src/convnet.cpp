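// Dense 2D conv-net kernels for the segmentation backbone.
// Layout conventions (must match the R side):
//  - activations: arma::cube H x W x C (R array [row, col, channel])
//  - 3x3 / 1x1 conv weights: mat (k*k*Cin) x Cout, row index = ky + k*kx + k*k*ci
//  - 2x2 transposed-conv weights: mat (4*Cin) x Cout, row index = pos + 4*ci,
//    pos = ky + 2*kx; output pixel (2i+ky, 2j+kx)
// im2col + BLAS gemm; padding (k-1)/2 so spatial size is preserved.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  mat Xc(H * W, k * k * C, fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int col = ky + k * kx + k * k * ci;
        const int di = ky - pad, dj = kx - pad;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di) - 1;
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj) - 1;
        if (i1 < i0 || j1 < j0) continue;
        for (int j = j0; j <= j1; ++j) {
          Xc.col(col).subvec(i0 + H * j, i1 + H * j) =
            x.slice(ci).col(j + dj).subvec(i0 + di, i1 + di);
        }
      }
    }
  }
  return Xc;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, const int k) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Cout = W.n_cols;
  mat Y = im2col(x, k) * W;
  Y.each_row() += b.t();
  cube out(H, Wd, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = reshape(Y.col(co), H, Wd);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& W,
                      const arma::cube& gy, const int k) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  const int Cout = gy.n_slices;
  mat Gy(H * Wd, Cout);
  for (int co = 0; co < Cout; ++co)
    Gy.col(co) = vectorise(gy.slice(co));
  mat Xc = im2col(x, k);
  mat gW = Xc.t() * Gy;
  vec gb = sum(Gy, 0).t();
  mat GXc = Gy * W.t();
  cube gx(H, Wd, C, fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int col = ky + k * kx + k * k * ci;
        const int di = ky - pad, dj = kx - pad;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di) - 1;
        const int j0 = std::max(0, -dj), j1 = std::min((int)Wd, (int)Wd - dj) - 1;
        if (i1 < i0 || j1 < j0) continue;
        for (int j = j0; j <= j1; ++j) {
          gx.slice(ci).col(j + dj).subvec(i0 + di, i1 + di) +=
            GXc.col(col).subvec(i0 + H * j, i1 + H * j);
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// 2x2 max pooling, H and W even; idx stores the within-slice linear argmax.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
Rcpp::List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  icube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int i2 = 2 * i, j2 = 2 * j;
        double best = xs(i2, j2); int bi = i2, bj = j2;
        if (xs(i2 + 1, j2) > best) { best = xs(i2 + 1, j2); bi = i2 + 1; bj = j2; }
        if (xs(i2, j2 + 1) > best) { best = xs(i2, j2 + 1); bi = i2; bj = j2 + 1; }
        if (xs(i2 + 1, j2 + 1) > best) { best = xs(i2 + 1, j2 + 1); bi = i2 + 1; bj = j2 + 1; }
        y(i, j, c) = best;
        idx(i, j, c) = bi + H * bj;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
arma::cube maxpool2_bwd(const arma::icube& idx, const arma::cube& gy,
                        const int H, const int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        gx.slice(c)(idx(i, j, c)) += gy(i, j, c);
  return gx;
}

// [[Rcpp::export(name = ".upconv2_fwd")]]
arma::cube upconv2_fwd(const arma::cube& x, const arma::mat& W,
                       const arma::vec& b) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols;
  mat Xm(H * Wd, Cin);
  for (int ci = 0; ci < Cin; ++ci)
    Xm.col(ci) = vectorise(x.slice(ci));
  cube out(2 * H, 2 * Wd, Cout);
  for (int kx = 0; kx < 2; ++kx) {
    for (int ky = 0; ky < 2; ++ky) {
      const int pos = ky + 2 * kx;
      mat Wp(Cin, Cout);
      for (int ci = 0; ci < Cin; ++ci)
        Wp.row(ci) = W.row(pos + 4 * ci);
      mat Yp = Xm * Wp;
      // non-overlapping stride-2 kernel: each output pixel sees exactly one pos
      Yp.each_row() += b.t();
      for (int co = 0; co < Cout; ++co)
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            out(2 * i + ky, 2 * j + kx, co) = Yp(i + H * j, co);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".upconv2_bwd")]]
Rcpp::List upconv2_bwd(const arma::cube& x, const arma::mat& W,
                       const arma::cube& gy) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  mat Xm(H * Wd, Cin);
  for (int ci = 0; ci < Cin; ++ci)
    Xm.col(ci) = vectorise(x.slice(ci));
  mat gW(4 * Cin, Cout, fill::zeros);
  vec gb(Cout, fill::zeros);
  mat gXm(H * Wd, Cin, fill::zeros);
  for (int kx = 0; kx < 2; ++kx) {
    for (int ky = 0; ky < 2; ++ky) {
      const int pos = ky + 2 * kx;
      mat Gp(H * Wd, Cout);
      for (int co = 0; co < Cout; ++co)
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            Gp(i + H * j, co) = gy(2 * i + ky, 2 * j + kx, co);
      mat Wp(Cin, Cout);
      for (int ci = 0; ci < Cin; ++ci)
        Wp.row(ci) = W.row(pos + 4 * ci);
      mat gWp = Xm.t() * Gp;
      for (int ci = 0; ci < Cin; ++ci)
        gW.row(pos + 4 * ci) = gWp.row(ci);
      gb += sum(Gp, 0).t();
      gXm += Gp * Wp.t();
    }
  }
  cube gx(H, Wd, Cin);
  for (int ci = 0; ci < Cin; ++ci)
    gx.slice(ci) = reshape(gXm.col(ci), H, Wd);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}
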