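// U-Net for projection-domain virtual monoenergetic synthesis.
//
// Single-channel image-to-image network: `depth` contraction blocks (two
// 3x3 same-padded convs + ReLU each) with 2x2 max pooling between blocks,
// a mirrored expansion path using bilinear upsampling and channel
// concatenation of the matching contraction output, no batch norm, and a
// linear 1x1 output conv. Feature maps double per level from
// `base` to `base * 2^(depth-1)`. Trained with MAE loss and Adam.
//
// Implementation: im2col + GEMM convolutions in single precision.
// All randomness (init, shuffling) uses std::mt19937 with Box-Muller so
// results are bit-reproducible across platforms for a given seed.
#include <RcppArmadillo.h>
#include <random>
using namespace arma;

namespace {

struct RNG {
  std::mt19937 g;
  explicit RNG(unsigned seed) : g(seed) {}
  double unif() { return (g() + 0.5) / 4294967296.0; }
  double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

// 3x3 same-padding im2col: x is (H*W) x C, out is (H*W) x (9*C)
void im2col(const fmat& x, int H, int W, fmat& cols) {
  const int C = x.n_cols;
  cols.zeros(x.n_rows, 9 * C);
  for (int c = 0; c < C; ++c) {
    const fmat xs(const_cast<float*>(x.colptr(c)), H, W, false, true);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int r = c * 9 + (dj + 1) * 3 + (di + 1);
        fmat tgt(cols.colptr(r), H, W, false, true);
        int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        int j0 = std::max(0, -dj), j1 = W - 1 - std::max(0, dj);
        tgt.submat(i0, j0, i1, j1) = xs.submat(i0 + di, j0 + dj, i1 + di, j1 + dj);
      }
    }
  }
}

// transpose of im2col: accumulate (H*W) x (9*C) columns back into dx
void col2im(const fmat& cols, int H, int W, fmat& dx) {
  const int C = dx.n_cols;
  dx.zeros();
  for (int c = 0; c < C; ++c) {
    fmat dxs(dx.colptr(c), H, W, false, true);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int r = c * 9 + (dj + 1) * 3 + (di + 1);
        const fmat src(const_cast<float*>(cols.colptr(r)), H, W, false, true);
        int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
        int j0 = std::max(0, -dj), j1 = W - 1 - std::max(0, dj);
        dxs.submat(i0 + di, j0 + dj, i1 + di, j1 + dj) +=
            src.submat(i0, j0, i1, j1);
      }
    }
  }
}

struct Conv {           // weights (K*C_in) x C_out, bias C_out
  fmat W; frowvec b;
  int k;                // 1 or 3
};

struct UNetCfg { int depth, base, H, W; };

// channel width of encoder level i
inline int chan(const UNetCfg& c, int i) { return c.base << i; }

std::vector<Conv> init_net(const UNetCfg& c, unsigned seed) {
  std::vector<Conv> L;
  RNG rng(seed);
  auto mk = [&](int k, int cin, int cout) {
    Conv cv; cv.k = k;
    cv.W.set_size(k * k * cin, cout);
    double sd = std::sqrt(2.0 / (k * k * cin));   // He fan-in
    for (uword i = 0; i < cv.W.n_elem; ++i) cv.W[i] = sd * rng.norm();
    if (k == 1) cv.W.zeros();   // zero-initialized output head
    cv.b.zeros(cout);
    L.push_back(std::move(cv));
  };
  for (int i = 0; i < c.depth; ++i) {
    mk(3, i == 0 ? 1 : chan(c, i - 1), chan(c, i));
    mk(3, chan(c, i), chan(c, i));
  }
  for (int i = c.depth - 2; i >= 0; --i) {
    mk(3, chan(c, i + 1) + chan(c, i), chan(c, i));
    mk(3, chan(c, i), chan(c, i));
  }
  mk(1, c.base, 1);
  return L;
}

// --- primitive ops on (H*W) x C activations ---------------------------

void conv_fwd(const Conv& cv, const fmat& x, int H, int W, fmat& cols,
              fmat& y) {
  if (cv.k == 1) { y = x * cv.W; }
  else { im2col(x, H, W, cols); y = cols * cv.W; }
  y.each_row() += cv.b;
}

void pool_fwd(const fmat& x, int H, int W, fmat& y, umat& idx) {
  const int C = x.n_cols, Ho = H / 2, Wo = W / 2;
  y.set_size(Ho * Wo, C); idx.set_size(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const fmat xs(const_cast<float*>(x.colptr(c)), H, W, false, true);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        int bi = 2 * i, bj = 2 * j, ai = bi, aj = bj;
        float v = xs(bi, bj);
        if (xs(bi + 1, bj) > v) { v = xs(bi + 1, bj); ai = bi + 1; }
        if (xs(bi, bj + 1) > v) { v = xs(bi, bj + 1); aj = bj + 1; ai = bi; }
        if (xs(bi + 1, bj + 1) > v) { v = xs(bi + 1, bj + 1); ai = bi + 1; aj = bj + 1; }
        y(i + Ho * j, c) = v;
        idx(i + Ho * j, c) = ai + (uword)H * aj;
      }
  }
}

void pool_bwd(const fmat& dy, const umat& idx, int H, int W, fmat& dx) {
  const int C = dy.n_cols;
  dx.zeros(H * W, C);
  for (int c = 0; c < C; ++c)
    for (uword r = 0; r < dy.n_rows; ++r) dx(idx(r, c), c) += dy(r, c);
}

// bilinear x2 interpolation weights along one axis (half-pixel centers)
void up_axis(int n_out, int n_in, ivec& i0, ivec& i1, fvec& w1) {
  i0.set_size(n_out); i1.set_size(n_out); w1.set_size(n_out);
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    int a = (int)std::floor(s);
    double w = s - a;
    if (a < 0) { a = 0; w = 0.0; }
    if (a >= n_in - 1) { a = n_in - 2; w = 1.0; }
    i0[i] = a; i1[i] = a + 1; w1[i] = (float)w;
  }
}

void up_fwd(const fmat& x, int H, int W, fmat& y) {
  const int C = x.n_cols, Ho = 2 * H, Wo = 2 * W;
  ivec r0, r1, c0, c1; fvec wr, wc;
  up_axis(Ho, H, r0, r1, wr); up_axis(Wo, W, c0, c1, wc);
  y.set_size(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const fmat xs(const_cast<float*>(x.colptr(c)), H, W, false, true);
    fmat ys(y.colptr(c), Ho, Wo, false, true);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        ys(i, j) =
            (1 - wr[i]) * ((1 - wc[j]) * xs(r0[i], c0[j]) + wc[j] * xs(r0[i], c1[j])) +
            wr[i] * ((1 - wc[j]) * xs(r1[i], c0[j]) + wc[j] * xs(r1[i], c1[j]));
  }
}

void up_bwd(const fmat& dy, int H, int W, fmat& dx) {
  const int C = dy.n_cols, Ho = 2 * H, Wo = 2 * W;
  ivec r0, r1, c0, c1; fvec wr, wc;
  up_axis(Ho, H, r0, r1, wr); up_axis(Wo, W, c0, c1, wc);
  dx.zeros(H * W, C);
  for (int c = 0; c < C; ++c) {
    const fmat dys(const_cast<float*>(dy.colptr(c)), Ho, Wo, false, true);
    fmat dxs(dx.colptr(c), H, W, false, true);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        float g = dys(i, j);
        dxs(r0[i], c0[j]) += (1 - wr[i]) * (1 - wc[j]) * g;
        dxs(r0[i], c1[j]) += (1 - wr[i]) * wc[j] * g;
        dxs(r1[i], c0[j]) += wr[i] * (1 - wc[j]) * g;
        dxs(r1[i], c1[j]) += wr[i] * wc[j] * g;
      }
  }
}

// --- full forward/backward --------------------------------------------

struct Cache {
  std::vector<fmat> act;      // post-ReLU conv outputs, in layer order
  std::vector<fmat> cols;     // im2col matrices per conv layer
  std::vector<fmat> pooled;   // pooled activations per encoder level
  std::vector<umat> poolidx;
  std::vector<fmat> upped;    // concat inputs per decoder level
  fmat out;
};

fmat forward(const std::vector<Conv>& L, const UNetCfg& c, const fmat& x0,
             Cache* K) {
  Cache local; Cache& k = K ? *K : local;
  int nl = 2 * c.depth + 2 * (c.depth - 1) + 1;
  k.act.resize(nl); k.cols.resize(nl);
  k.pooled.resize(c.depth - 1); k.poolidx.resize(c.depth - 1);
  k.upped.resize(c.depth - 1);
  std::vector<fmat> skips(c.depth - 1);
  std::vector<std::pair<int,int>> skipdim(c.depth - 1);
  int H = c.H, W = c.W, li = 0;
  fmat x = x0;
  for (int i = 0; i < c.depth; ++i) {
    conv_fwd(L[li], x, H, W, k.cols[li], k.act[li]);
    k.act[li].transform([](float v) { return v > 0 ? v : 0.f; }); ++li;
    conv_fwd(L[li], k.act[li - 1], H, W, k.cols[li], k.act[li]);
    k.act[li].transform([](float v) { return v > 0 ? v : 0.f; }); ++li;
    if (i < c.depth - 1) {
      skips[i] = k.act[li - 1]; skipdim[i] = {H, W};
      pool_fwd(k.act[li - 1], H, W, k.pooled[i], k.poolidx[i]);
      x = k.pooled[i]; H /= 2; W /= 2;
    }
  }
  fmat cur = k.act[li - 1];
  for (int i = c.depth - 2; i >= 0; --i) {
    fmat up;
    up_fwd(cur, H, W, up);
    H *= 2; W *= 2;
    int d = c.depth - 2 - i;
    k.upped[d].set_size(up.n_rows, up.n_cols + skips[i].n_cols);
    k.upped[d].cols(0, up.n_cols - 1) = up;
    k.upped[d].cols(up.n_cols, k.upped[d].n_cols - 1) = skips[i];
    conv_fwd(L[li], k.upped[d], H, W, k.cols[li], k.act[li]);
    k.act[li].transform([](float v) { return v > 0 ? v : 0.f; }); ++li;
    conv_fwd(L[li], k.act[li - 1], H, W, k.cols[li], k.act[li]);
    k.act[li].transform([](float v) { return v > 0 ? v : 0.f; }); ++li;
    cur = k.act[li - 1];
  }
  conv_fwd(L[li], cur, H, W, k.cols[li], k.out);
  return k.out;
}

void backward(const std::vector<Conv>& L, const UNetCfg& c, const fmat& x0,
              const Cache& k, const fmat& dout, std::vector<Conv>& G) {
  const int nl = (int)L.size();
  int H = c.H, W = c.W;
  // output 1x1 conv
  int li = nl - 1;
  G[li].W += k.act[li - 1].t() * dout;
  G[li].b += sum(dout, 0);
  fmat d = dout * L[li].W.t();
  --li;
  // decoder blocks (from shallowest back to deepest)
  std::vector<fmat> skipgrad(c.depth - 1);
  for (int i = 0; i <= c.depth - 2; ++i) {
    // level i decoder operates at full-res/2^i
    int Hh = c.H >> i, Ww = c.W >> i;
    int dlev = c.depth - 2 - i;                  // index into upped
    for (int rep = 0; rep < 2; ++rep) {
      d %= conv_to<fmat>::from(k.act[li] > 0);   // ReLU mask
      const fmat& input = (rep == 0) ? k.act[li - 1] : k.upped[dlev];
      // dW via the cached im2col of this layer
      G[li].W += k.cols[li].t() * d;
      G[li].b += sum(d, 0);
      fmat dcols = d * L[li].W.t();
      fmat dx(input.n_rows, input.n_cols);
      col2im(dcols, Hh, Ww, dx);
      d = std::move(dx);
      --li;
    }
    // split concat gradient: [up | skip]
    int cup = chan(c, i + 1);
    fmat dup = d.cols(0, cup - 1);
    skipgrad[i] = d.cols(cup, d.n_cols - 1);
    fmat dprev;
    up_bwd(dup, Hh / 2, Ww / 2, dprev);
    d = std::move(dprev);
  }
  // encoder blocks, deepest first
  for (int i = c.depth - 1; i >= 0; --i) {
    int Hh = c.H >> i, Ww = c.W >> i;
    if (i < c.depth - 1) {
      fmat dpool;
      pool_bwd(d, k.poolidx[i], Hh, Ww, dpool);
      d = std::move(dpool);
      d += skipgrad[i];
    }
    for (int rep = 0; rep < 2; ++rep) {
      d %= conv_to<fmat>::from(k.act[li] > 0);
      G[li].W += k.cols[li].t() * d;
      G[li].b += sum(d, 0);
      fmat dcols = d * L[li].W.t();
      int cin = L[li].W.n_rows / 9;
      fmat dx(Hh * Ww, cin);
      col2im(dcols, Hh, Ww, dx);
      d = std::move(dx);
      --li;
    }
  }
}

std::vector<Conv> weights_from_R(Rcpp::List wl) {
  std::vector<Conv> L;
  for (int i = 0; i < wl.size(); ++i) {
    Rcpp::List e = wl[i];
    Conv cv;
    cv.W = conv_to<fmat>::from(Rcpp::as<mat>(e["W"]));
    cv.b = conv_to<frowvec>::from(Rcpp::as<rowvec>(e["b"]));
    cv.k = Rcpp::as<int>(e["k"]);
    L.push_back(std::move(cv));
  }
  return L;
}

Rcpp::List weights_to_R(const std::vector<Conv>& L) {
  Rcpp::List out(L.size());
  for (size_t i = 0; i < L.size(); ++i) {
    out[i] = Rcpp::List::create(
        Rcpp::Named("W") = conv_to<mat>::from(L[i].W),
        Rcpp::Named("b") = conv_to<rowvec>::from(L[i].b),
        Rcpp::Named("k") = L[i].k);
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_unet_init(int depth, int base, int H, int W, int seed) {
  UNetCfg c{depth, base, H, W};
  return weights_to_R(init_net(c, (unsigned)seed));
}

// x: H x W x N array; returns H x W x N predictions
// [[Rcpp::export]]
arma::cube cpp_unet_forward(Rcpp::List weights, const arma::cube& x,
                            int depth, int base) {
  UNetCfg c{depth, base, (int)x.n_rows, (int)x.n_cols};
  std::vector<Conv> L = weights_from_R(weights);
  cube out(x.n_rows, x.n_cols, x.n_slices);
  for (uword n = 0; n < x.n_slices; ++n) {
    fmat xin = conv_to<fmat>::from(vectorise(x.slice(n)));
    fmat y = forward(L, c, xin, nullptr);
    out.slice(n) = reshape(conv_to<mat>::from(y.col(0)), x.n_rows, x.n_cols);
  }
  return out;
}

// Adam training with MAE loss and best-validation checkpointing.
// x, y: H x W x N; train_idx/val_idx are 1-based slice indices.
// Returns list(weights = best-validation weights, history, best_epoch).
// [[Rcpp::export]]
Rcpp::List cpp_unet_train(Rcpp::List weights, const arma::cube& x,
                          const arma::cube& y, arma::ivec train_idx,
                          arma::ivec val_idx, int depth, int base,
                          int epochs, double lr, int lr_schedule, double beta1, double beta2,
                          int batch_size, int seed, int patience,
                          bool verbose) {
  UNetCfg c{depth, base, (int)x.n_rows, (int)x.n_cols};
  std::vector<Conv> L = weights_from_R(weights);
  const int nl = (int)L.size();
  std::vector<Conv> G(nl), M(nl), V(nl);
  for (int i = 0; i < nl; ++i) {
    G[i].W.zeros(size(L[i].W)); G[i].b.zeros(L[i].b.n_elem);
    M[i] = G[i]; V[i] = G[i];
    G[i].k = M[i].k = V[i].k = L[i].k;
  }
  const int ntr = train_idx.n_elem, nva = val_idx.n_elem;
  const double eps = 1e-8;
  RNG rng((unsigned)seed);
  std::vector<int> order(ntr);
  for (int i = 0; i < ntr; ++i) order[i] = train_idx[i] - 1;
  Rcpp::NumericVector htrain(epochs, NA_REAL), hval(epochs, NA_REAL);
  double best_val = std::numeric_limits<double>::infinity();
  std::vector<Conv> best = L;
  int best_epoch = 0, stall = 0, adam_t = 0, ran = 0;
  Cache K;

  for (int ep = 0; ep < epochs; ++ep) {
    double lr_ep = lr;
    if (lr_schedule == 1) {
      // linear warmup over the first 5% of epochs (guards the high
      // initial rate against early dead-ReLU collapse), then cosine
      // annealing to lr/100 over the remainder
      int warm = std::max(1, epochs / 20);
      if (ep < warm) {
        lr_ep = lr * (ep + 1.0) / warm;
      } else {
        double frac = epochs - 1 > warm ?
            (double)(ep - warm) / (epochs - 1 - warm) : 1.0;
        lr_ep = 0.01 * lr + 0.99 * lr * 0.5 * (1.0 + std::cos(M_PI * frac));
      }
    }
    // Fisher-Yates shuffle with the portable generator
    for (int i = ntr - 1; i > 0; --i) {
      int j = (int)(rng.unif() * (i + 1));
      std::swap(order[i], order[j]);
    }
    double trsum = 0.0;
    for (int b0 = 0; b0 < ntr; b0 += batch_size) {
      int bn = std::min(batch_size, ntr - b0);
      for (int i = 0; i < nl; ++i) { G[i].W.zeros(); G[i].b.zeros(); }
      for (int bi = 0; bi < bn; ++bi) {
        int n = order[b0 + bi];
        fmat xin = conv_to<fmat>::from(vectorise(x.slice(n)));
        fmat tgt = conv_to<fmat>::from(vectorise(y.slice(n)));
        fmat pred = forward(L, c, xin, &K);
        fmat r = pred - tgt;
        trsum += accu(abs(r)) / r.n_elem;
        fmat dout = sign(r) / (float)(r.n_elem * bn);
        backward(L, c, xin, K, dout, G);
      }
      ++adam_t;
      double bc1 = 1 - std::pow(beta1, adam_t);
      double bc2 = 1 - std::pow(beta2, adam_t);
      for (int i = 0; i < nl; ++i) {
        M[i].W = beta1 * M[i].W + (1 - beta1) * G[i].W;
        V[i].W = beta2 * V[i].W + (1 - beta2) * square(G[i].W);
        L[i].W -= lr_ep * (M[i].W / bc1) / (sqrt(V[i].W / bc2) + eps);
        M[i].b = beta1 * M[i].b + (1 - beta1) * G[i].b;
        V[i].b = beta2 * V[i].b + (1 - beta2) * square(G[i].b);
        L[i].b -= lr_ep * (M[i].b / bc1) / (sqrt(V[i].b / bc2) + eps);
      }
    }
    if (!std::isfinite(trsum))
      Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
    htrain[ep] = trsum / ntr;
    double vsum = 0.0;
    for (int i = 0; i < nva; ++i) {
      int n = val_idx[i] - 1;
      fmat xin = conv_to<fmat>::from(vectorise(x.slice(n)));
      fmat pred = forward(L, c, xin, nullptr);
      fmat tgt = conv_to<fmat>::from(vectorise(y.slice(n)));
      vsum += accu(abs(pred - tgt)) / tgt.n_elem;
    }
    double vmae = nva > 0 ? vsum / nva : htrain[ep];
    hval[ep] = vmae;
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << " train MAE " << htrain[ep]
                  << " val MAE " << vmae << "\n";
    if (vmae < best_val) {
      best_val = vmae; best = L; best_epoch = ep + 1; stall = 0;
    } else if (++stall >= patience && patience > 0) {
      ran = ep + 1;
      break;
    }
    ran = ep + 1;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = weights_to_R(best),
      Rcpp::Named("train_mae") = htrain[Rcpp::Range(0, ran - 1)],
      Rcpp::Named("val_mae") = hval[Rcpp::Range(0, ran - 1)],
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val_mae") = best_val);
}
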