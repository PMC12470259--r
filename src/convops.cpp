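// Low-level tensor kernels for the segmentation network.
//
// Layout conventions (shared with the R side):
//   * activations are arma::cube (H, W, C), column-major, matching an R
//     array with dim c(H, W, C);
//   * k x k convolution weights arrive as a (k*k*Cin) x Cout matrix whose
//     row index is ky + k*kx + k*k*ci — i.e. an R array dim c(k,k,Cin,Cout)
//     flattened with matrix();
//   * 2x2 transposed-convolution weights arrive as a (4*Cin) x Cout matrix,
//     row index a + 2*b + 4*ci for output offset (a, b).
// All convolutions use zero same-padding and stride 1 so printed feature-map
// sizes hold exactly; upsampling is stride-2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::uword;
using arma::vec;

// im2col for same-padded k x k patches: rows = pixels (h + H*w), cols =
// patch entries (ky + k*kx + k*k*ci).
static mat im2col_same(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  mat P(static_cast<uword>(H) * W, static_cast<uword>(k) * k * C,
        arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const mat& xs = x.slice(ci);
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const uword col = ky + k * kx + k * k * ci;
        const int dy = ky - pad, dx = kx - pad;
        const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
        const int w0 = std::max(0, -dx), w1 = std::min(W, W - dx);
        for (int w = w0; w < w1; ++w) {
          double* dst = P.colptr(col) + static_cast<uword>(w) * H;
          const double* src = xs.colptr(w + dx) + dy;
          std::copy(src + h0, src + h1, dst + h0);
        }
      }
    }
  }
  return P;
}

// scatter-add of a patch-matrix back onto an image (adjoint of im2col_same)
static cube col2im_same(const mat& P, const int H, const int W, const int C,
                        const int k) {
  const int pad = (k - 1) / 2;
  cube x(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    mat& xs = x.slice(ci);
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const uword col = ky + k * kx + k * k * ci;
        const int dy = ky - pad, dx = kx - pad;
        const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
        const int w0 = std::max(0, -dx), w1 = std::min(W, W - dx);
        for (int w = w0; w < w1; ++w) {
          double* dst = xs.colptr(w + dx) + dy;
          const double* src = P.colptr(col) + static_cast<uword>(w) * H;
          for (int h = h0; h < h1; ++h) dst[h] += src[h];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export(name = ".cpp_conv2d")]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, const int k) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Cout = W.n_cols;
  mat P = im2col_same(x, k);
  mat O = P * W;            // (H*W) x Cout
  O.each_row() += b.t();
  return cube(O.memptr(), H, Wd, Cout);  // copies into shape
}

// [[Rcpp::export(name = ".cpp_conv2d_backward")]]
Rcpp::List cpp_conv2d_backward(const arma::cube& x, const arma::mat& W,
                               const int k, const arma::cube& gout) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = gout.n_slices;
  mat G(const_cast<double*>(gout.memptr()),
        static_cast<uword>(H) * Wd, Cout, false, true);
  mat P = im2col_same(x, k);
  mat gW = P.t() * G;
  vec gb = arma::sum(G, 0).t();
  mat GP = G * W.t();                    // (H*W) x (k*k*Cin)
  cube gx = col2im_same(GP, H, Wd, Cin, k);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 stride-2 transposed convolution: out(2h+a, 2w+b, co) +=
//   sum_ci x(h, w, ci) * W[(a + 2b + 4ci), co]
// [[Rcpp::export(name = ".cpp_convT2x2")]]
arma::cube cpp_convT2x2(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols;
  mat X(const_cast<double*>(x.memptr()),
        static_cast<uword>(H) * Wd, Cin, false, true);
  cube out(2 * H, 2 * Wd, Cout);
  for (int co = 0; co < Cout; ++co) out.slice(co).fill(b[co]);
  for (int a2 = 0; a2 < 2; ++a2) {
    for (int b2 = 0; b2 < 2; ++b2) {
      arma::uvec rows(Cin);
      for (int ci = 0; ci < Cin; ++ci) rows[ci] = a2 + 2 * b2 + 4 * ci;
      mat O = X * W.rows(rows);  // (H*W) x Cout
      for (int co = 0; co < Cout; ++co) {
        mat& os = out.slice(co);
        for (int w = 0; w < Wd; ++w) {
          double* dst = os.colptr(2 * w + b2) + a2;
          const double* src = O.colptr(co) + static_cast<uword>(w) * H;
          for (int h = 0; h < H; ++h) dst[2 * h] += src[h];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_convT2x2_backward")]]
Rcpp::List cpp_convT2x2_backward(const arma::cube& x, const arma::mat& W,
                                 const arma::cube& gout) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = gout.n_slices;
  mat X(const_cast<double*>(x.memptr()),
        static_cast<uword>(H) * Wd, Cin, false, true);
  mat gW(4 * Cin, Cout, arma::fill::zeros);
  mat gX(static_cast<uword>(H) * Wd, Cin, arma::fill::zeros);
  vec gb(Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) gb[co] = arma::accu(gout.slice(co));
  for (int a2 = 0; a2 < 2; ++a2) {
    for (int b2 = 0; b2 < 2; ++b2) {
      mat G(static_cast<uword>(H) * Wd, Cout);
      for (int co = 0; co < Cout; ++co) {
        const mat& gs = gout.slice(co);
        for (int w = 0; w < Wd; ++w) {
          const double* src = gs.colptr(2 * w + b2) + a2;
          double* dst = G.colptr(co) + static_cast<uword>(w) * H;
          for (int h = 0; h < H; ++h) dst[h] = src[2 * h];
        }
      }
      arma::uvec rows(Cin);
      for (int ci = 0; ci < Cin; ++ci) rows[ci] = a2 + 2 * b2 + 4 * ci;
      gW.rows(rows) = X.t() * G;
      gX += G * W.rows(rows).t();
    }
  }
  cube gx(gX.memptr(), H, Wd, Cin);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; returns pooled cube and flat argmax indices
// (1-based into each H x W plane) for the backward pass.
// [[Rcpp::export(name = ".cpp_maxpool2")]]
Rcpp::List cpp_maxpool2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube out(Ho, Wo, C);
  arma::ucube amax(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const int h2 = 2 * h, w2 = 2 * w;
        double best = xs(h2, w2);
        uword bi = h2 + static_cast<uword>(w2) * H;
        if (xs(h2 + 1, w2) > best) { best = xs(h2 + 1, w2); bi = h2 + 1 + static_cast<uword>(w2) * H; }
        if (xs(h2, w2 + 1) > best) { best = xs(h2, w2 + 1); bi = h2 + static_cast<uword>(w2 + 1) * H; }
        if (xs(h2 + 1, w2 + 1) > best) { best = xs(h2 + 1, w2 + 1); bi = h2 + 1 + static_cast<uword>(w2 + 1) * H; }
        out(h, w, c) = best;
        amax(h, w, c) = bi + 1;  // 1-based
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".cpp_maxpool2_backward")]]
arma::cube cpp_maxpool2_backward(const arma::ucube& argmax,
                                 const arma::cube& gout,
                                 const int H, const int W) {
  const int C = gout.n_slices;
  cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& gs = gx.slice(c);
    const mat& go = gout.slice(c);
    const arma::umat& am = argmax.slice(c);
    for (uword j = 0; j < go.n_elem; ++j)
      gs(am(j) - 1) += go(j);
  }
  return gx;
}

// Channel-wise max and mean pooling: (H, W, C) -> (H, W, 2) descriptor pair
// [max, mean]; argmax channel (1-based) kept for the backward pass.
// [[Rcpp::export(name = ".cpp_channel_pool")]]
Rcpp::List cpp_channel_pool(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(H, W, 2);
  arma::umat amax(H, W);
  mat mx = x.slice(0), mean = x.slice(0);
  amax.fill(1);
  for (int c = 1; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (uword j = 0; j < mx.n_elem; ++j) {
      if (xs(j) > mx(j)) { mx(j) = xs(j); amax(j) = c + 1; }
      mean(j) += xs(j);
    }
  }
  out.slice(0) = mx;
  out.slice(1) = mean / C;
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".cpp_channel_pool_backward")]]
arma::cube cpp_channel_pool_backward(const arma::cube& g2,
                                     const arma::umat& argmax, const int C) {
  const int H = g2.n_rows, W = g2.n_cols;
  cube gx(H, W, C, arma::fill::zeros);
  const mat& gmax = g2.slice(0);
  const mat gmean = g2.slice(1) / C;
  for (int c = 0; c < C; ++c) gx.slice(c) = gmean;
  for (uword j = 0; j < gmax.n_elem; ++j) {
    const int c = argmax(j) - 1;
    gx(j % H, (j / H) % W, c) += gmax(j);
  }
  return gx;
}
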