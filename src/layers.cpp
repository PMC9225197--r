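// Network primitives for the CardioNet encoder-decoder.
//
// Tensor convention: feature maps are R arrays with dim c(H, W, C, N),
// column-major, so each (c, n) slice is a contiguous H x W matrix and each
// sample n is a contiguous H*W*C block.  Convolutions are realized as
// im2col + GEMM; the im2col matrix is (H*W) x (k*k*C) with column index
// q = c*k*k + (kj+pad)*k + (ki+pad), and conv weights are stored as a
// (k*k*Cin) x Cout matrix so that  Y = im2col(X) %*% W  writes the output
// slice directly in array layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector tensor_dim(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d tensor (H, W, C, N)");
  return d;
}

static NumericVector make_tensor(int H, int W, int C, int N) {
  NumericVector y((R_xlen_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

static IntegerVector make_itensor(int H, int W, int C, int N) {
  IntegerVector y((R_xlen_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

// im2col for one sample: xp points at an H*W*C block.
static arma::mat im2col(const double* xp, int H, int W, int C, int k) {
  const int pad = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  const int k2 = k * k;
  arma::mat col((size_t)HW, (size_t)k2 * C);
  if (k == 1) {
    std::memcpy(col.memptr(), xp, sizeof(double) * HW * C);
    return col;
  }
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xs = xp + (size_t)c * HW;
    for (int kj = -pad; kj <= pad; ++kj) {
      for (int ki = -pad; ki <= pad; ++ki) {
        const int q = c * k2 + (kj + pad) * k + (ki + pad);
        double* cp = col.colptr(q);
        const int w0 = std::max(0, -kj), w1 = std::min(W, W - kj);
        const int h0 = std::max(0, -ki), h1 = std::min(H, H - ki);
        if (h1 <= h0) continue;
        for (int w = w0; w < w1; ++w) {
          const double* src = xs + (size_t)(w + kj) * H + (h0 + ki);
          std::memcpy(cp + (size_t)w * H + h0, src,
                      sizeof(double) * (size_t)(h1 - h0));
        }
      }
    }
  }
  return col;
}

// scatter-add the columns of `col` back onto an image block (gradient of
// im2col).
static void col2im_add(const arma::mat& col, double* xp, int H, int W, int C,
                       int k) {
  const int pad = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  const int k2 = k * k;
  if (k == 1) {
    const double* cp = col.memptr();
    for (size_t i = 0; i < HW * C; ++i) xp[i] += cp[i];
    return;
  }
  for (int c = 0; c < C; ++c) {
    double* xs = xp + (size_t)c * HW;
    for (int kj = -pad; kj <= pad; ++kj) {
      for (int ki = -pad; ki <= pad; ++ki) {
        const int q = c * k2 + (kj + pad) * k + (ki + pad);
        const double* cp = col.colptr(q);
        const int w0 = std::max(0, -kj), w1 = std::min(W, W - kj);
        const int h0 = std::max(0, -ki), h1 = std::min(H, H - ki);
        if (h1 <= h0) continue;
        for (int w = w0; w < w1; ++w) {
          double* dst = xs + (size_t)(w + kj) * H + (h0 + ki);
          const double* src = cp + (size_t)w * H + h0;
          for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cn_conv_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                          int k) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (w.nrow() != k * k * C) stop("weight rows do not match k*k*in_channels");
  const int Cout = w.ncol();
  NumericVector y = make_tensor(H, W, Cout, N);
  arma::mat wm(w.begin(), w.nrow(), Cout, false);
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (size_t)n * HW * C, H, W, C, k);
    arma::mat ym(y.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    ym = col * wm;
    if (b.size() > 0)
      for (int c = 0; c < Cout; ++c) ym.col(c) += b[c];
  }
  return y;
}

// [[Rcpp::export]]
List cn_conv_bwd(NumericVector x, NumericMatrix w, NumericVector dy, int k,
                 bool need_dx, bool has_bias) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = w.ncol();
  const size_t HW = (size_t)H * W;
  arma::mat wm(w.begin(), w.nrow(), Cout, false);
  NumericMatrix dw(w.nrow(), Cout);
  arma::mat dwm(dw.begin(), w.nrow(), Cout, false, true);
  NumericVector db(has_bias ? Cout : 0);
  NumericVector dx;
  if (need_dx) dx = make_tensor(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (size_t)n * HW * C, H, W, C, k);
    arma::mat dym(dy.begin() + (size_t)n * HW * Cout, HW, Cout, false);
    dwm += col.t() * dym;
    if (has_bias)
      for (int c = 0; c < Cout; ++c) db[c] += arma::accu(dym.col(c));
    if (need_dx) {
      arma::mat dcol = dym * wm.t();
      col2im_add(dcol, dx.begin() + (size_t)n * HW * C, H, W, C, k);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// depth-wise 3x3 convolution, one filter per channel; wd is 9 x C with the
// same within-kernel ordering as im2col.
// [[Rcpp::export]]
NumericVector cn_dwconv_fwd(NumericVector x, NumericMatrix wd) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (wd.nrow() != 9 || wd.ncol() != C) stop("depth-wise weights must be 9 x C");
  NumericVector y = make_tensor(H, W, C, N);
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const arma::mat xs(const_cast<double*>(x.begin()) +
                             ((size_t)n * C + c) * HW,
                         H, W, false);
      arma::mat ys(y.begin() + ((size_t)n * C + c) * HW, H, W, false, true);
      for (int kj = -1; kj <= 1; ++kj)
        for (int ki = -1; ki <= 1; ++ki) {
          const double wv = wd((kj + 1) * 3 + (ki + 1), c);
          const int r0 = std::max(0, -ki), r1 = std::min(H, H - ki);
          const int c0 = std::max(0, -kj), c1 = std::min(W, W - kj);
          if (r1 <= r0 || c1 <= c0) continue;
          ys.submat(r0, c0, r1 - 1, c1 - 1) +=
              wv * xs.submat(r0 + ki, c0 + kj, r1 - 1 + ki, c1 - 1 + kj);
        }
    }
  return y;
}

// [[Rcpp::export]]
List cn_dwconv_bwd(NumericVector x, NumericMatrix wd, NumericVector dy,
                   bool need_dx) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericMatrix dwd(9, C);
  NumericVector dx;
  if (need_dx) dx = make_tensor(H, W, C, N);
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      const arma::mat xs(const_cast<double*>(x.begin()) + off, H, W, false);
      const arma::mat dys(const_cast<double*>(dy.begin()) + off, H, W, false);
      for (int kj = -1; kj <= 1; ++kj)
        for (int ki = -1; ki <= 1; ++ki) {
          const int q = (kj + 1) * 3 + (ki + 1);
          const int r0 = std::max(0, -ki), r1 = std::min(H, H - ki);
          const int c0 = std::max(0, -kj), c1 = std::min(W, W - kj);
          if (r1 <= r0 || c1 <= c0) continue;
          dwd(q, c) += arma::accu(
              dys.submat(r0, c0, r1 - 1, c1 - 1) %
              xs.submat(r0 + ki, c0 + kj, r1 - 1 + ki, c1 - 1 + kj));
          if (need_dx) {
            arma::mat dxs(dx.begin() + off, H, W, false, true);
            dxs.submat(r0 + ki, c0 + kj, r1 - 1 + ki, c1 - 1 + kj) +=
                wd(q, c) * dys.submat(r0, c0, r1 - 1, c1 - 1);
          }
        }
    }
  return List::create(_["dx"] = dx, _["dw"] = dwd);
}

// 2x2 max pooling with stride 2 (floor semantics: a trailing odd row/col is
// dropped, as MATLAB does).  idx records the 0-based linear position of the
// maximum within the input H x W slice, so unpooling can restore it.
// [[Rcpp::export]]
List cn_maxpool_fwd(NumericVector x) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = make_tensor(Ho, Wo, C, N);
  IntegerVector idx = make_itensor(Ho, Wo, C, N);
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * HW;
      double* ys = y.begin() + ((size_t)n * C + c) * HWo;
      int* is = idx.begin() + ((size_t)n * C + c) * HWo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          int best = (2 * wo) * H + 2 * ho;
          double bv = xs[best];
          const int cand[3] = {(2 * wo) * H + 2 * ho + 1,
                               (2 * wo + 1) * H + 2 * ho,
                               (2 * wo + 1) * H + 2 * ho + 1};
          for (int t = 0; t < 3; ++t)
            if (xs[cand[t]] > bv) { bv = xs[cand[t]]; best = cand[t]; }
          ys[(size_t)wo * Ho + ho] = bv;
          is[(size_t)wo * Ho + ho] = best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Scatter values (or gradients) back to the recorded positions; used both as
// max-unpooling forward and as max-pooling backward.
// [[Rcpp::export]]
NumericVector cn_pool_scatter(NumericVector v, IntegerVector idx, int H,
                              int W) {
  IntegerVector d = tensor_dim(v);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector out = make_tensor(H, W, C, N);
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* vs = v.begin() + ((size_t)n * C + c) * HWo;
      const int* is = idx.begin() + ((size_t)n * C + c) * HWo;
      double* os = out.begin() + ((size_t)n * C + c) * HW;
      for (size_t p = 0; p < HWo; ++p) os[is[p]] += vs[p];
    }
  return out;
}

// Gather from recorded positions; used as max-unpooling backward.
// [[Rcpp::export]]
NumericVector cn_pool_gather(NumericVector g, IntegerVector idx) {
  IntegerVector d = tensor_dim(g);  // g is H x W x C x N
  IntegerVector di = idx.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = di[0], Wo = di[1];
  NumericVector out = make_tensor(Ho, Wo, C, N);
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gs = g.begin() + ((size_t)n * C + c) * HW;
      const int* is = idx.begin() + ((size_t)n * C + c) * HWo;
      double* os = out.begin() + ((size_t)n * C + c) * HWo;
      for (size_t p = 0; p < HWo; ++p) os[p] = gs[is[p]];
    }
  return out;
}

// Batch normalization over (H, W, N) per channel.
// [[Rcpp::export]]
List cn_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
               NumericVector rmean, NumericVector rvar, double momentum,
               double eps, bool training) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  NumericVector y = make_tensor(H, W, C, N);
  NumericVector bmean(C), binvstd(C), nrmean(clone(rmean)), nrvar(clone(rvar));
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xs = x.begin() + ((size_t)n * C + c) * HW;
        for (size_t p = 0; p < HW; ++p) { s += xs[p]; s2 += xs[p] * xs[p]; }
      }
      m = s / M;
      v = s2 / M - m * m;
      if (v < 0) v = 0;
      nrmean[c] = (1 - momentum) * rmean[c] + momentum * m;
      nrvar[c] = (1 - momentum) * rvar[c] + momentum * v;
    } else {
      m = rmean[c];
      v = rvar[c];
    }
    const double invstd = 1.0 / std::sqrt(v + eps);
    bmean[c] = m;
    binvstd[c] = invstd;
    const double a = gamma[c] * invstd, b0 = beta[c] - a * m;
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + ((size_t)n * C + c) * HW;
      double* ys = y.begin() + ((size_t)n * C + c) * HW;
      for (size_t p = 0; p < HW; ++p) ys[p] = a * xs[p] + b0;
    }
  }
  return List::create(_["y"] = y, _["mean"] = bmean, _["invstd"] = binvstd,
                      _["rmean"] = nrmean, _["rvar"] = nrvar);
}

// [[Rcpp::export]]
List cn_bn_bwd(NumericVector x, NumericVector dy, NumericVector gamma,
               NumericVector bmean, NumericVector binvstd) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  NumericVector dx = make_tensor(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = bmean[c], is = binvstd[c];
    double sdy = 0, sdyx = 0;
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + ((size_t)n * C + c) * HW;
      const double* ds = dy.begin() + ((size_t)n * C + c) * HW;
      for (size_t p = 0; p < HW; ++p) {
        sdy += ds[p];
        sdyx += ds[p] * (xs[p] - m) * is;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    const double g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + ((size_t)n * C + c) * HW;
      const double* ds = dy.begin() + ((size_t)n * C + c) * HW;
      double* dxs = dx.begin() + ((size_t)n * C + c) * HW;
      for (size_t p = 0; p < HW; ++p) {
        const double xhat = (xs[p] - m) * is;
        dxs[p] = g * is * (ds[p] - sdy / M - xhat * sdyx / M);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cn_relu_fwd(NumericVector x) {
  NumericVector y = clone(x);
  for (R_xlen_t i = 0; i < y.size(); ++i)
    if (y[i] < 0) y[i] = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cn_relu_bwd(NumericVector y, NumericVector dy) {
  NumericVector dx = clone(dy);
  for (R_xlen_t i = 0; i < dx.size(); ++i)
    if (y[i] <= 0) dx[i] = 0;
  return dx;
}

// Channel-wise concatenation along dim 3.
// [[Rcpp::export]]
NumericVector cn_concat(List xs) {
  const int P = xs.size();
  std::vector<NumericVector> vs(P);
  int H = 0, W = 0, N = 0, Ctot = 0;
  std::vector<int> Cs(P);
  for (int p = 0; p < P; ++p) {
    vs[p] = as<NumericVector>(xs[p]);
    IntegerVector d = tensor_dim(vs[p]);
    if (p == 0) { H = d[0]; W = d[1]; N = d[3]; }
    else if (d[0] != H || d[1] != W || d[3] != N)
      stop("concat inputs disagree in H, W or N");
    Cs[p] = d[2];
    Ctot += d[2];
  }
  NumericVector y = make_tensor(H, W, Ctot, N);
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    size_t coff = 0;
    for (int p = 0; p < P; ++p) {
      std::memcpy(y.begin() + ((size_t)n * Ctot + coff) * HW,
                  vs[p].begin() + (size_t)n * Cs[p] * HW,
                  sizeof(double) * HW * Cs[p]);
      coff += Cs[p];
    }
  }
  return y;
}

// [[Rcpp::export]]
List cn_split(NumericVector x, IntegerVector sizes) {
  IntegerVector d = tensor_dim(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int P = sizes.size();
  int tot = 0;
  for (int p = 0; p < P; ++p) tot += sizes[p];
  if (tot != C) stop("split sizes do not sum to channel count");
  List out(P);
  const size_t HW = (size_t)H * W;
  int coff = 0;
  for (int p = 0; p < P; ++p) {
    NumericVector part = make_tensor(H, W, sizes[p], N);
    for (int n = 0; n < N; ++n)
      std::memcpy(part.begin() + (size_t)n * sizes[p] * HW,
                  x.begin() + ((size_t)n * C + coff) * HW,
                  sizeof(double) * HW * sizes[p]);
    out[p] = part;
    coff += sizes[p];
  }
  return out;
}

// Per-pixel softmax with class-weighted cross-entropy.  labels are 1-based
// class indices (H x W x N); wclass has one weight per class.  The loss is
// normalized by the total weight so its scale is comparable across batches.
// [[Rcpp::export]]
List cn_softmax_ce(NumericVector scores, IntegerVector labels,
                   NumericVector wclass, bool need_grad) {
  IntegerVector d = tensor_dim(scores);
  const int H = d[0], W = d[1], K = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector probs = make_tensor(H, W, K, N);
  NumericVector dscores;
  if (need_grad) dscores = make_tensor(H, W, K, N);
  double loss = 0, wsum = 0;
  long correct = 0;
  for (int n = 0; n < N; ++n) {
    const double* sn = scores.begin() + (size_t)n * K * HW;
    double* pn = probs.begin() + (size_t)n * K * HW;
    const int* ln = labels.begin() + (size_t)n * HW;
    for (size_t p = 0; p < HW; ++p) {
      double mx = sn[p];
      int amax = 0;
      for (int k = 1; k < K; ++k) {
        const double v = sn[p + k * HW];
        if (v > mx) { mx = v; amax = k; }
      }
      double Z = 0;
      for (int k = 0; k < K; ++k) {
        const double e = std::exp(sn[p + k * HW] - mx);
        pn[p + k * HW] = e;
        Z += e;
      }
      for (int k = 0; k < K; ++k) pn[p + k * HW] /= Z;
      const int y = ln[p] - 1;
      if (y < 0 || y >= K) stop("label out of range");
      if (amax == y) ++correct;
      const double wy = wclass[y];
      loss -= wy * std::log(std::max(pn[p + y * HW], 1e-12));
      wsum += wy;
    }
  }
  if (need_grad) {
    for (int n = 0; n < N; ++n) {
      const double* pn = probs.begin() + (size_t)n * K * HW;
      double* gn = dscores.begin() + (size_t)n * K * HW;
      const int* ln = labels.begin() + (size_t)n * HW;
      for (size_t p = 0; p < HW; ++p) {
        const int y = ln[p] - 1;
        const double wy = wclass[y] / wsum;
        for (int k = 0; k < K; ++k)
          gn[p + k * HW] = wy * (pn[p + k * HW] - (k == y ? 1.0 : 0.0));
      }
    }
  }
  return List::create(_["loss"] = loss / wsum, _["probs"] = probs,
                      _["dscores"] = dscores,
                      _["pixel_accuracy"] = (double)correct / (HW * N));
}

// Plain per-pixel softmax (inference).
// [[Rcpp::export]]
NumericVector cn_softmax(NumericVector scores) {
  IntegerVector d = tensor_dim(scores);
  const int H = d[0], W = d[1], K = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector probs = make_tensor(H, W, K, N);
  for (int n = 0; n < N; ++n) {
    const double* sn = scores.begin() + (size_t)n * K * HW;
    double* pn = probs.begin() + (size_t)n * K * HW;
    for (size_t p = 0; p < HW; ++p) {
      double mx = sn[p];
      for (int k = 1; k < K; ++k) mx = std::max(mx, sn[p + k * HW]);
      double Z = 0;
      for (int k = 0; k < K; ++k) {
        const double e = std::exp(sn[p + k * HW] - mx);
        pn[p + k * HW] = e;
        Z += e;
      }
      for (int k = 0; k < K; ++k) pn[p + k * HW] /= Z;
    }
  }
  return probs;
}

// Argmax over the class dimension with ties broken toward the lower class
// index; returns 1-based labels (H x W x N).
// [[Rcpp::export]]
IntegerVector cn_argmax(NumericVector scores) {
  IntegerVector d = tensor_dim(scores);
  const int H = d[0], W = d[1], K = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  IntegerVector lab(Dimension(H, W, N));
  for (int n = 0; n < N; ++n) {
    const double* sn = scores.begin() + (size_t)n * K * HW;
    int* ln = lab.begin() + (size_t)n * HW;
    for (size_t p = 0; p < HW; ++p) {
      int amax = 0;
      double mx = sn[p];
      for (int k = 1; k < K; ++k)
        if (sn[p + k * HW] > mx) { mx = sn[p + k * HW]; amax = k; }
      ln[p] = amax + 1;
    }
  }
  return lab;
}
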