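// Single-precision training executor.
//
// The double-precision primitives in layers.cpp define the reference
// semantics of every operation and are what the test-suite gradient checks
// exercise.  Training, however, is dominated by memory traffic, so the full
// graph (forward, weighted softmax cross-entropy, backward, gradient
// clipping, Adam) also exists here as a float32 executor with preallocated
// workspace: activations live in arma::fmat buffers of shape (H*W, C*N)
// whose column n*C + c is the H x W map of channel c of sample n -- the
// same memory layout as the R arrays, reinterpreted as float.  Tests assert
// that the two paths agree to single precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

enum Kind { CONV = 0, DWSEP = 1, POOL = 2, UNPOOL = 3, CONCAT = 4 };

// float im2col into a caller-provided buffer; layout as in layers.cpp
void im2col_f(const float* xp, int H, int W, int C, int k, arma::fmat& col) {
  const int pad = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  const int k2 = k * k;
  col.set_size(HW, (size_t)k2 * C);
  if (k == 1) {
    std::memcpy(col.memptr(), xp, sizeof(float) * HW * C);
    return;
  }
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const float* xs = xp + (size_t)c * HW;
    for (int kj = -pad; kj <= pad; ++kj)
      for (int ki = -pad; ki <= pad; ++ki) {
        const int q = c * k2 + (kj + pad) * k + (ki + pad);
        float* cp = col.colptr(q);
        const int w0 = std::max(0, -kj), w1 = std::min(W, W - kj);
        const int h0 = std::max(0, -ki), h1 = std::min(H, H - ki);
        if (h1 <= h0) continue;
        for (int w = w0; w < w1; ++w)
          std::memcpy(cp + (size_t)w * H + h0,
                      xs + (size_t)(w + kj) * H + (h0 + ki),
                      sizeof(float) * (size_t)(h1 - h0));
      }
  }
}

void col2im_add_f(const arma::fmat& col, float* xp, int H, int W, int C,
                  int k) {
  const int pad = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  const int k2 = k * k;
  if (k == 1) {
    const float* cp = col.memptr();
    for (size_t i = 0; i < HW * C; ++i) xp[i] += cp[i];
    return;
  }
  for (int c = 0; c < C; ++c) {
    float* xs = xp + (size_t)c * HW;
    for (int kj = -pad; kj <= pad; ++kj)
      for (int ki = -pad; ki <= pad; ++ki) {
        const int q = c * k2 + (kj + pad) * k + (ki + pad);
        const float* cp = col.colptr(q);
        const int w0 = std::max(0, -kj), w1 = std::min(W, W - kj);
        const int h0 = std::max(0, -ki), h1 = std::min(H, H - ki);
        if (h1 <= h0) continue;
        for (int w = w0; w < w1; ++w) {
          float* dst = xs + (size_t)(w + kj) * H + (h0 + ki);
          const float* src = cp + (size_t)w * H + h0;
          for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
        }
      }
  }
}

struct AdamTensor {
  arma::fmat m, v;
  bool init = false;
};

struct Layer {
  std::string name;
  int kind = CONV;
  int k = 3;
  int Cin = 0, Cout = 0;
  int inH = 0, inW = 0, H = 0, W = 0;
  int input = -1;  // -1 = network input
  int pair = -1;   // paired pool index for unpool
  bool bn = false;
  std::vector<int> sources;  // concat

  // parameters (float mirrors of the R doubles)
  arma::fmat Wt;   // conv: (k2*Cin) x Cout; dwsep: 9 x Cin (depth-wise part)
  arma::fmat Wp;   // dwsep point-wise: Cin x Cout
  arma::fvec b, gamma, beta, rmean, rvar;

  // workspace
  arma::fmat act, z, mid, gact;
  bool ghas = false;
  arma::fvec bnmean, bninvstd;
  arma::Mat<arma::uword> idx;

  // gradients + Adam state
  arma::fmat gWt, gWp;
  arma::fvec gb, ggamma, gbeta;
  AdamTensor aWt, aWp, ab, agamma, abeta;
};

struct Model {
  int inH = 0, inW = 0, inC = 0, maxN = 0, N = 0;
  long t = 0;  // Adam step counter
  std::vector<Layer> layers;
  arma::fmat X;     // input (HW x C*N)
  arma::fmat gin;   // unused gradient sink for the input
  arma::fmat colbuf, dcolbuf, probs;
};

arma::fmat& act_of(Model& M, int idx) {
  return idx < 0 ? M.X : M.layers[idx].act;
}

// gradient buffer of a layer's output, zero-initialized on first touch
arma::fmat* grad_of(Model& M, int idx) {
  if (idx < 0) return nullptr;
  Layer& L = M.layers[idx];
  if (!L.ghas) {
    L.gact.zeros((size_t)L.H * L.W, (size_t)L.Cout * M.N);
    L.ghas = true;
  }
  return &L.gact;
}

void bn_relu_forward(Model& M, Layer& L, bool training, float momentum,
                     float eps) {
  const int N = M.N, C = L.Cout;
  const size_t HW = (size_t)L.H * L.W;
  L.bnmean.set_size(C);
  L.bninvstd.set_size(C);
  const double Mtot = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const float* zp = L.z.colptr((size_t)n * C + c);
        for (size_t p = 0; p < HW; ++p) {
          s += zp[p];
          s2 += (double)zp[p] * zp[p];
        }
      }
      m = s / Mtot;
      v = s2 / Mtot - m * m;
      if (v < 0) v = 0;
      L.rmean[c] = (1 - momentum) * L.rmean[c] + momentum * m;
      L.rvar[c] = (1 - momentum) * L.rvar[c] + momentum * v;
    } else {
      m = L.rmean[c];
      v = L.rvar[c];
    }
    const float invstd = 1.0f / std::sqrt((float)v + eps);
    L.bnmean[c] = m;
    L.bninvstd[c] = invstd;
    const float a = L.gamma[c] * invstd;
    const float b0 = L.beta[c] - a * (float)m;
    for (int n = 0; n < N; ++n) {
      const float* zp = L.z.colptr((size_t)n * C + c);
      float* yp = L.act.colptr((size_t)n * C + c);
      for (size_t p = 0; p < HW; ++p) {
        const float y = a * zp[p] + b0;
        yp[p] = y > 0.f ? y : 0.f;
      }
    }
  }
}

void forward(Model& M, bool training, float momentum, float eps) {
  const int N = M.N;
  for (size_t li = 0; li < M.layers.size(); ++li) {
    Layer& L = M.layers[li];
    const size_t HW = (size_t)L.H * L.W;
    const size_t inHW = (size_t)L.inH * L.inW;
    arma::fmat& IN = act_of(M, L.input);
    switch (L.kind) {
      case CONV: {
        L.z.set_size(HW, (size_t)L.Cout * N);
        for (int n = 0; n < N; ++n) {
          im2col_f(IN.colptr((size_t)n * L.Cin), L.inH, L.inW, L.Cin, L.k,
                   M.colbuf);
          arma::fmat zv(L.z.colptr((size_t)n * L.Cout), HW, L.Cout, false,
                        true);
          zv = M.colbuf * L.Wt;
          if (!L.bn)
            for (int c = 0; c < L.Cout; ++c) zv.col(c) += L.b[c];
        }
        L.act.set_size(HW, (size_t)L.Cout * N);
        if (L.bn) bn_relu_forward(M, L, training, momentum, eps);
        else L.act = L.z;
        break;
      }
      case DWSEP: {
        L.mid.zeros(inHW, (size_t)L.Cin * N);
        for (size_t j = 0; j < (size_t)L.Cin * N; ++j) {
          const int c = j % L.Cin;
          const arma::fmat xs(const_cast<float*>(IN.colptr(j)), L.inH, L.inW,
                              false);
          arma::fmat ys(L.mid.colptr(j), L.inH, L.inW, false, true);
          for (int kj = -1; kj <= 1; ++kj)
            for (int ki = -1; ki <= 1; ++ki) {
              const float wv = L.Wt((kj + 1) * 3 + (ki + 1), c);
              const int r0 = std::max(0, -ki), r1 = std::min(L.inH, L.inH - ki);
              const int c0 = std::max(0, -kj), c1 = std::min(L.inW, L.inW - kj);
              if (r1 <= r0 || c1 <= c0) continue;
              ys.submat(r0, c0, r1 - 1, c1 - 1) +=
                  wv * xs.submat(r0 + ki, c0 + kj, r1 - 1 + ki, c1 - 1 + kj);
            }
        }
        L.z.set_size(HW, (size_t)L.Cout * N);
        for (int n = 0; n < N; ++n) {
          arma::fmat mv(L.mid.colptr((size_t)n * L.Cin), HW, L.Cin, false);
          arma::fmat zv(L.z.colptr((size_t)n * L.Cout), HW, L.Cout, false,
                        true);
          zv = mv * L.Wp;
          if (!L.bn)
            for (int c = 0; c < L.Cout; ++c) zv.col(c) += L.b[c];
        }
        L.act.set_size(HW, (size_t)L.Cout * N);
        if (L.bn) bn_relu_forward(M, L, training, momentum, eps);
        else L.act = L.z;
        break;
      }
      case POOL: {
        const int Ho = L.H, Wo = L.W, Hi = L.inH;
        L.act.set_size(HW, (size_t)L.Cout * N);
        L.idx.set_size(HW, (size_t)L.Cout * N);
        for (size_t j = 0; j < (size_t)L.Cout * N; ++j) {
          const float* xs = IN.colptr(j);
          float* ys = L.act.colptr(j);
          arma::uword* is = L.idx.colptr(j);
          for (int wo = 0; wo < Wo; ++wo)
            for (int ho = 0; ho < Ho; ++ho) {
              size_t best = (size_t)(2 * wo) * Hi + 2 * ho;
              float bv = xs[best];
              const size_t cand[3] = {best + 1, best + Hi, best + Hi + 1};
              for (int tcd = 0; tcd < 3; ++tcd)
                if (xs[cand[tcd]] > bv) { bv = xs[cand[tcd]]; best = cand[tcd]; }
              ys[(size_t)wo * Ho + ho] = bv;
              is[(size_t)wo * Ho + ho] = best;
            }
        }
        break;
      }
      case UNPOOL: {
        const Layer& P = M.layers[L.pair];
        L.act.zeros(HW, (size_t)L.Cout * N);
        for (size_t j = 0; j < (size_t)L.Cout * N; ++j) {
          const float* xs = IN.colptr(j);
          const arma::uword* is = P.idx.colptr(j);
          float* ys = L.act.colptr(j);
          for (size_t p = 0; p < inHW; ++p) ys[is[p]] += xs[p];
        }
        break;
      }
      case CONCAT: {
        L.act.set_size(HW, (size_t)L.Cout * N);
        for (int n = 0; n < N; ++n) {
          size_t off = 0;
          for (int sidx : L.sources) {
            const Layer& S = M.layers[sidx];
            std::memcpy(L.act.colptr((size_t)n * L.Cout + off),
                        S.act.colptr((size_t)n * S.Cout),
                        sizeof(float) * HW * S.Cout);
            off += S.Cout;
          }
        }
        break;
      }
    }
  }
}

void backward(Model& M) {
  const int N = M.N;
  for (int li = (int)M.layers.size() - 1; li >= 0; --li) {
    Layer& L = M.layers[li];
    if (!L.ghas) continue;
    const size_t HW = (size_t)L.H * L.W;
    const size_t inHW = (size_t)L.inH * L.inW;
    arma::fmat& g = L.gact;
    if (L.kind == CONCAT) {
      for (int n = 0; n < N; ++n) {
        size_t off = 0;
        for (int sidx : L.sources) {
          Layer& S = M.layers[sidx];
          arma::fmat* gs = grad_of(M, sidx);
          for (int c = 0; c < S.Cout; ++c) {
            float* dst = gs->colptr((size_t)n * S.Cout + c);
            const float* src = g.colptr((size_t)n * L.Cout + off + c);
            for (size_t p = 0; p < HW; ++p) dst[p] += src[p];
          }
          off += S.Cout;
        }
      }
      continue;
    }
    if (L.kind == POOL) {
      arma::fmat* gi = grad_of(M, L.input);
      for (size_t j = 0; j < (size_t)L.Cout * N; ++j) {
        const float* gp = g.colptr(j);
        const arma::uword* is = L.idx.colptr(j);
        float* dst = gi->colptr(j);
        for (size_t p = 0; p < HW; ++p) dst[is[p]] += gp[p];
      }
      continue;
    }
    if (L.kind == UNPOOL) {
      const Layer& P = M.layers[L.pair];
      arma::fmat* gi = grad_of(M, L.input);
      for (size_t j = 0; j < (size_t)L.Cout * N; ++j) {
        const float* gp = g.colptr(j);
        const arma::uword* is = P.idx.colptr(j);
        float* dst = gi->colptr(j);
        for (size_t p = 0; p < inHW; ++p) dst[p] += gp[is[p]];
      }
      continue;
    }
    // convolutional unit: undo ReLU + BN first
    if (L.bn) {
      const int C = L.Cout;
      const double Mtot = (double)HW * N;
      L.ggamma.zeros(C);
      L.gbeta.zeros(C);
      for (int c = 0; c < C; ++c) {
        const float m = L.bnmean[c], is = L.bninvstd[c];
        double sdy = 0, sdyx = 0;
        for (int n = 0; n < N; ++n) {
          const size_t j = (size_t)n * C + c;
          float* gp = g.colptr(j);
          const float* yp = L.act.colptr(j);
          const float* zp = L.z.colptr(j);
          for (size_t p = 0; p < HW; ++p) {
            if (yp[p] <= 0.f) gp[p] = 0.f;  // ReLU mask
            sdy += gp[p];
            sdyx += (double)gp[p] * (zp[p] - m) * is;
          }
        }
        L.ggamma[c] = sdyx;
        L.gbeta[c] = sdy;
        const float gmul = L.gamma[c] * is;
        const float c1 = (float)(sdy / Mtot), c2 = (float)(sdyx / Mtot);
        for (int n = 0; n < N; ++n) {
          const size_t j = (size_t)n * C + c;
          float* gp = g.colptr(j);
          const float* zp = L.z.colptr(j);
          for (size_t p = 0; p < HW; ++p) {
            const float xhat = (zp[p] - m) * is;
            gp[p] = gmul * (gp[p] - c1 - xhat * c2);
          }
        }
      }
    } else {
      L.gb.zeros(L.Cout);
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < L.Cout; ++c)
          L.gb[c] += arma::accu(g.col((size_t)n * L.Cout + c));
    }
    arma::fmat& IN = act_of(M, L.input);
    arma::fmat* gi = L.input >= 0 ? grad_of(M, L.input) : nullptr;
    if (L.kind == CONV) {
      L.gWt.zeros(arma::size(L.Wt));
      for (int n = 0; n < N; ++n) {
        im2col_f(IN.colptr((size_t)n * L.Cin), L.inH, L.inW, L.Cin, L.k,
                 M.colbuf);
        arma::fmat gv(g.colptr((size_t)n * L.Cout), HW, L.Cout, false);
        L.gWt += M.colbuf.t() * gv;
        if (gi) {
          M.dcolbuf = gv * L.Wt.t();
          col2im_add_f(M.dcolbuf, gi->colptr((size_t)n * L.Cin), L.inH, L.inW,
                       L.Cin, L.k);
        }
      }
    } else {  // DWSEP
      L.gWp.zeros(arma::size(L.Wp));
      L.gWt.zeros(arma::size(L.Wt));
      arma::fmat gmid((size_t)inHW, (size_t)L.Cin * N);
      for (int n = 0; n < N; ++n) {
        arma::fmat mv(L.mid.colptr((size_t)n * L.Cin), HW, L.Cin, false);
        arma::fmat gv(g.colptr((size_t)n * L.Cout), HW, L.Cout, false);
        L.gWp += mv.t() * gv;
        arma::fmat gmv(gmid.colptr((size_t)n * L.Cin), HW, L.Cin, false,
                       true);
        gmv = gv * L.Wp.t();
      }
      for (size_t j = 0; j < (size_t)L.Cin * N; ++j) {
        const int c = j % L.Cin;
        const arma::fmat xs(const_cast<float*>(IN.colptr(j)), L.inH, L.inW,
                            false);
        const arma::fmat dys(gmid.colptr(j), L.inH, L.inW, false);
        for (int kj = -1; kj <= 1; ++kj)
          for (int ki = -1; ki <= 1; ++ki) {
            const int q = (kj + 1) * 3 + (ki + 1);
            const int r0 = std::max(0, -ki), r1 = std::min(L.inH, L.inH - ki);
            const int c0 = std::max(0, -kj), c1 = std::min(L.inW, L.inW - kj);
            if (r1 <= r0 || c1 <= c0) continue;
            L.gWt(q, c) += arma::accu(
                dys.submat(r0, c0, r1 - 1, c1 - 1) %
                xs.submat(r0 + ki, c0 + kj, r1 - 1 + ki, c1 - 1 + kj));
            if (gi) {
              arma::fmat dxs(gi->colptr(j), L.inH, L.inW, false, true);
              dxs.submat(r0 + ki, c0 + kj, r1 - 1 + ki, c1 - 1 + kj) +=
                  L.Wt(q, c) * dys.submat(r0, c0, r1 - 1, c1 - 1);
            }
          }
      }
    }
  }
}

void adam_update(AdamTensor& A, arma::fmat& P, const arma::fmat& G,
                 float scale, float lr, float b1, float b2, float eps,
                 float bc1, float bc2) {
  if (!A.init) {
    A.m.zeros(arma::size(P));
    A.v.zeros(arma::size(P));
    A.init = true;
  }
  arma::fmat g = G * scale;
  A.m = b1 * A.m + (1 - b1) * g;
  A.v = b2 * A.v + (1 - b2) * (g % g);
  P -= lr * (A.m / bc1) / (arma::sqrt(A.v / bc2) + eps);
}

Model* get_model(SEXP ptr) {
  Rcpp::XPtr<Model> xp(ptr);
  return xp.get();
}

}  // namespace

// [[Rcpp::export]]
SEXP cn_model_build(List layers, int inH, int inW, int inC, int maxN) {
  Model* M = new Model();
  M->inH = inH;
  M->inW = inW;
  M->inC = inC;
  M->maxN = maxN;
  size_t colmax = 1;
  for (int i = 0; i < layers.size(); ++i) {
    List ld = layers[i];
    Layer L;
    L.name = as<std::string>(ld["name"]);
    L.kind = as<int>(ld["kind"]);
    L.k = as<int>(ld["k"]);
    L.Cin = as<int>(ld["cin"]);
    L.Cout = as<int>(ld["cout"]);
    L.inH = as<int>(ld["in_h"]);
    L.inW = as<int>(ld["in_w"]);
    L.H = as<int>(ld["h"]);
    L.W = as<int>(ld["w"]);
    L.input = as<int>(ld["input"]);
    L.pair = as<int>(ld["pair"]);
    L.bn = as<bool>(ld["bn"]);
    L.sources = as<std::vector<int> >(ld["sources"]);
    if (L.kind == CONV)
      colmax = std::max(colmax,
                        (size_t)L.inH * L.inW * L.k * L.k * L.Cin);
    M->layers.push_back(L);
  }
  M->colbuf.set_size(1, 1);
  M->dcolbuf.set_size(1, 1);
  (void)colmax;
  return Rcpp::XPtr<Model>(M, true);
}

// [[Rcpp::export]]
void cn_model_set_params(SEXP ptr, List par) {
  Model* M = get_model(ptr);
  for (Layer& L : M->layers) {
    if (L.kind != CONV && L.kind != DWSEP) continue;
    List p = par[L.name];
    if (L.kind == CONV) {
      NumericMatrix W = p["W"];
      L.Wt = arma::conv_to<arma::fmat>::from(
          arma::mat(W.begin(), W.nrow(), W.ncol(), false));
    } else {
      NumericMatrix Wd = p["Wd"];
      NumericMatrix Wp = p["Wp"];
      L.Wt = arma::conv_to<arma::fmat>::from(
          arma::mat(Wd.begin(), Wd.nrow(), Wd.ncol(), false));
      L.Wp = arma::conv_to<arma::fmat>::from(
          arma::mat(Wp.begin(), Wp.nrow(), Wp.ncol(), false));
    }
    if (L.bn) {
      L.gamma = arma::conv_to<arma::fvec>::from(as<arma::vec>(p["gamma"]));
      L.beta = arma::conv_to<arma::fvec>::from(as<arma::vec>(p["beta"]));
      L.rmean = arma::conv_to<arma::fvec>::from(as<arma::vec>(p["rmean"]));
      L.rvar = arma::conv_to<arma::fvec>::from(as<arma::vec>(p["rvar"]));
    } else {
      L.b = arma::conv_to<arma::fvec>::from(as<arma::vec>(p["b"]));
    }
  }
}

// [[Rcpp::export]]
List cn_model_get_params(SEXP ptr) {
  Model* M = get_model(ptr);
  List out;
  for (Layer& L : M->layers) {
    if (L.kind != CONV && L.kind != DWSEP) continue;
    List p;
    if (L.kind == CONV) {
      p["W"] = wrap(arma::conv_to<arma::mat>::from(L.Wt));
    } else {
      p["Wd"] = wrap(arma::conv_to<arma::mat>::from(L.Wt));
      p["Wp"] = wrap(arma::conv_to<arma::mat>::from(L.Wp));
    }
    if (L.bn) {
      p["gamma"] = wrap(arma::conv_to<arma::vec>::from(L.gamma));
      p["beta"] = wrap(arma::conv_to<arma::vec>::from(L.beta));
      p["rmean"] = wrap(arma::conv_to<arma::vec>::from(L.rmean));
      p["rvar"] = wrap(arma::conv_to<arma::vec>::from(L.rvar));
    } else {
      p["b"] = wrap(arma::conv_to<arma::vec>::from(L.b));
    }
    out[L.name] = p;
  }
  return out;
}

static void load_input(Model* M, NumericVector x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("input must be a 4-d array");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H != M->inH || W != M->inW || C != M->inC)
    stop("input dims do not match the model");
  if (N > M->maxN) stop("batch larger than the executor's maximum");
  M->N = N;
  M->X.set_size((size_t)H * W, (size_t)C * N);
  const double* xp = x.begin();
  float* fp = M->X.memptr();
  const size_t tot = (size_t)H * W * C * N;
  for (size_t i = 0; i < tot; ++i) fp[i] = (float)xp[i];
}

// [[Rcpp::export]]
List cn_model_forward(SEXP ptr, NumericVector x, bool training,
                      double bn_momentum, double bn_eps) {
  Model* M = get_model(ptr);
  load_input(M, x);
  forward(*M, training, (float)bn_momentum, (float)bn_eps);
  Layer& L = M->layers.back();
  const size_t HW = (size_t)L.H * L.W;
  NumericVector scores((R_xlen_t)(HW * L.Cout * M->N));
  scores.attr("dim") = IntegerVector::create(L.H, L.W, L.Cout, M->N);
  const float* sp = L.act.memptr();
  double* op = scores.begin();
  for (size_t i = 0; i < HW * L.Cout * M->N; ++i) op[i] = sp[i];
  return List::create(_["scores"] = scores);
}

// [[Rcpp::export]]
List cn_model_train_step(SEXP ptr, NumericVector x, IntegerVector labels,
                         NumericVector wclass, double lr, double beta1,
                         double beta2, double adam_eps, double clip,
                         double clip_eps, double bn_momentum, double bn_eps) {
  Model* M = get_model(ptr);
  load_input(M, x);
  forward(*M, true, (float)bn_momentum, (float)bn_eps);

  // weighted softmax cross-entropy on the final scores
  Layer& L = M->layers.back();
  const int K = L.Cout, N = M->N;
  const size_t HW = (size_t)L.H * L.W;
  if ((size_t)labels.size() != HW * N) stop("label array size mismatch");
  for (Layer& Lx : M->layers) Lx.ghas = false;
  arma::fmat* g = grad_of(*M, (int)M->layers.size() - 1);
  double loss = 0, wsum = 0;
  long correct = 0;
  std::vector<float> pr(K);
  for (int n = 0; n < N; ++n) {
    const int* ln = labels.begin() + (size_t)n * HW;
    for (size_t p = 0; p < HW; ++p) {
      float mx = L.act(p, (size_t)n * K);
      int amax = 0;
      for (int k = 1; k < K; ++k) {
        const float v = L.act(p, (size_t)n * K + k);
        if (v > mx) { mx = v; amax = k; }
      }
      float Z = 0;
      for (int k = 0; k < K; ++k) {
        pr[k] = std::exp(L.act(p, (size_t)n * K + k) - mx);
        Z += pr[k];
      }
      const int y = ln[p] - 1;
      if (y < 0 || y >= K) stop("label out of range");
      if (amax == y) ++correct;
      const double wy = wclass[y];
      loss -= wy * std::log(std::max((double)pr[y] / Z, 1e-12));
      wsum += wy;
      for (int k = 0; k < K; ++k)
        (*g)(p, (size_t)n * K + k) = wy * (pr[k] / Z - (k == y ? 1.f : 0.f));
    }
  }
  *g /= (float)wsum;
  loss /= wsum;

  backward(*M);

  // global L2 clipping + Adam
  double sq = 0;
  for (Layer& Lx : M->layers) {
    if (Lx.kind != CONV && Lx.kind != DWSEP) continue;
    sq += arma::accu(arma::conv_to<arma::mat>::from(Lx.gWt % Lx.gWt));
    if (Lx.kind == DWSEP)
      sq += arma::accu(arma::conv_to<arma::mat>::from(Lx.gWp % Lx.gWp));
    if (Lx.bn) {
      sq += arma::accu(arma::conv_to<arma::vec>::from(Lx.ggamma % Lx.ggamma));
      sq += arma::accu(arma::conv_to<arma::vec>::from(Lx.gbeta % Lx.gbeta));
    } else {
      sq += arma::accu(arma::conv_to<arma::vec>::from(Lx.gb % Lx.gb));
    }
  }
  const double gnorm = std::sqrt(sq);
  float scale = 1.f;
  if (R_finite(clip) && gnorm > clip) scale = clip / (gnorm + clip_eps);
  M->t += 1;
  const float bc1 = 1 - std::pow((float)beta1, (float)M->t);
  const float bc2 = 1 - std::pow((float)beta2, (float)M->t);
  for (Layer& Lx : M->layers) {
    if (Lx.kind != CONV && Lx.kind != DWSEP) continue;
    adam_update(Lx.aWt, Lx.Wt, Lx.gWt, scale, lr, beta1, beta2, adam_eps,
                bc1, bc2);
    if (Lx.kind == DWSEP)
      adam_update(Lx.aWp, Lx.Wp, Lx.gWp, scale, lr, beta1, beta2, adam_eps,
                  bc1, bc2);
    if (Lx.bn) {
      arma::fmat gm(Lx.gamma.memptr(), Lx.gamma.n_elem, 1, false, true);
      arma::fmat bm(Lx.beta.memptr(), Lx.beta.n_elem, 1, false, true);
      arma::fmat ggm(Lx.ggamma.memptr(), Lx.ggamma.n_elem, 1, false);
      arma::fmat gbm(Lx.gbeta.memptr(), Lx.gbeta.n_elem, 1, false);
      adam_update(Lx.agamma, gm, ggm, scale, lr, beta1, beta2, adam_eps,
                  bc1, bc2);
      adam_update(Lx.abeta, bm, gbm, scale, lr, beta1, beta2, adam_eps,
                  bc1, bc2);
    } else {
      arma::fmat bv(Lx.b.memptr(), Lx.b.n_elem, 1, false, true);
      arma::fmat gbv(Lx.gb.memptr(), Lx.gb.n_elem, 1, false);
      adam_update(Lx.ab, bv, gbv, scale, lr, beta1, beta2, adam_eps, bc1,
                  bc2);
    }
  }
  return List::create(_["loss"] = loss,
                      _["pixel_accuracy"] = (double)correct / (HW * N),
                      _["gnorm"] = gnorm);
}
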