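// Fused convolution block: cross-correlation (same padding) -> batch
// norm -> ReLU -> max-pool -> inverted dropout, with backprop caches
// kept on the C++ side in an external pointer.
//
// The convolution runs in single precision as K shifted GEMMs over a
// zero-padded slab: each sequence occupies L + 2*pad consecutive
// columns of a (C, (L+2*pad)*B) matrix with zeroed borders, so a
// shifted column range never reads a neighbouring sequence and no
// im2col/col2im materialization is needed. Garbage written into the
// border columns of the output slab is never read. Training dynamics
// at single precision are standard for SGD-family optimizers; all
// parameters and reductions returned to R are double.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct ConvCache {
  std::vector<uint16_t> idx;  // one-hot channel index per slab column
  bool onehot = false;
  arma::fmat xp;       // padded input slab (C, Lp2*B)
  arma::fmat xhat;     // normalized pre-activation (F, L*B)
  arma::fmat act;      // post-ReLU, pre-pool (F, L*B)
  arma::fvec invstd;
  arma::vec bn_mean;
  arma::vec bn_var;
  arma::umat pool_idx; // argmax positions (F, Lp*B)
  arma::fmat mask;     // dropout mask on the block output
  int C, K, L, B, pad, pool_size, pool_stride;
  bool pooled;
};

// x: (C, L, B) R array as cube; returns padded float slab.
static void make_slab(const arma::cube& x, int pad, arma::fmat& xp) {
  const int C = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int Lp2 = L + 2 * pad;
  xp.zeros(C, (arma::uword)Lp2 * B);
  const double* src = x.memptr();
  for (int s = 0; s < B; ++s) {
    float* dst = xp.colptr((arma::uword)s * Lp2 + pad);
    const double* sp = src + (arma::uword)s * C * L;
    const arma::uword n = (arma::uword)C * L;
    for (arma::uword i = 0; i < n; ++i) dst[i] = (float)sp[i];
  }
}

// One-hot DNA input: extract the active channel per slab column
// (C = 4; the value 4 marks padding). Returns false when the input is
// not strictly one-hot, in which case the generic GEMM path is used.
static bool slab_onehot_idx(const arma::cube& x, int pad,
                            std::vector<uint16_t>& idx) {
  const int C = x.n_rows, L = x.n_cols, B = x.n_slices;
  if (C != 4) return false;
  const int Lp2 = L + 2 * pad;
  idx.assign((size_t)Lp2 * B, 4);
  const double* src = x.memptr();
  for (int s = 0; s < B; ++s) {
    uint16_t* ip = idx.data() + (size_t)s * Lp2 + pad;
    const double* sp = src + (size_t)s * C * L;
    for (int j = 0; j < L; ++j) {
      const double* col = sp + (size_t)j * C;
      int hot = -1;
      for (int c = 0; c < C; ++c) {
        if (col[c] == 1.0) {
          if (hot >= 0) return false;
          hot = c;
        } else if (col[c] != 0.0) {
          return false;
        }
      }
      if (hot < 0) return false;
      ip[j] = (uint16_t)hot;
    }
  }
  return true;
}

// Gather-accumulate convolution for one-hot input: y slab column g
// receives W(:, k*C + idx[g + k - pad]) for every tap k.
static void conv_slab_onehot(const arma::fmat& W,
                             const std::vector<uint16_t>& idx, int C,
                             int K, int pad, int F, arma::uword ncol,
                             arma::fmat& y) {
  y.zeros(F, ncol);
  const arma::uword n = ncol - 2 * pad;
  for (arma::uword g = 0; g < n; ++g) {
    float* yp = y.colptr(g + pad);
    for (int k = 0; k < K; ++k) {
      const uint16_t c = idx[g + k];
      if (c >= C) continue;
      const float* wp = W.colptr((arma::uword)k * C + c);
      for (int f = 0; f < F; ++f) yp[f] += wp[f];
    }
  }
}

// K shifted GEMMs: y(:, g) = sum_k Wk * xp(:, g + k - pad) over the
// interior range; y must be a (F, Lp2*B) slab.
static void conv_slab(const arma::fmat& W, const arma::fmat& xp, int C,
                      int K, int pad, arma::fmat& y) {
  const arma::uword ncol = xp.n_cols;
  const arma::uword n = ncol - 2 * pad;  // interior width
  y.zeros(W.n_rows, ncol);
  arma::fmat yv(y.colptr(pad), W.n_rows, n, false, true);
  for (int k = 0; k < K; ++k) {
    const arma::fmat Wk(const_cast<float*>(W.colptr((arma::uword)k * C)),
                        W.n_rows, C, false, true);
    const arma::fmat xv(const_cast<float*>(xp.colptr(k)), C, n, false,
                        true);
    yv += Wk * xv;
  }
}

// [[Rcpp::export]]
List conv_block_forward_cpp(const arma::cube& x, const arma::mat& W,
                            const arma::vec& b, const arma::vec& gamma,
                            const arma::vec& beta, double eps,
                            int pool_size, int pool_stride,
                            bool use_dropout, double drop_rate) {
  const int C = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int F = W.n_rows;
  const int K = W.n_cols / C;
  const int pad = (K - 1) / 2;
  const int Lp2 = L + 2 * pad;
  const arma::uword N = (arma::uword)L * B;
  XPtr<ConvCache> cache(new ConvCache(), true);
  cache->C = C; cache->K = K; cache->L = L; cache->B = B;
  cache->pad = pad; cache->pool_size = pool_size;
  cache->pool_stride = pool_stride;
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
  arma::fmat yslab;
  cache->onehot = slab_onehot_idx(x, pad, cache->idx);
  if (cache->onehot) {
    conv_slab_onehot(Wf, cache->idx, C, K, pad, F,
                     (arma::uword)Lp2 * B, yslab);
  } else {
    make_slab(x, pad, cache->xp);
    conv_slab(Wf, cache->xp, C, K, pad, yslab);
  }
  // batch-norm statistics over data columns (conv bias folded in)
  arma::vec sum(F, arma::fill::zeros), sumsq(F, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    const float* yp = yslab.colptr((arma::uword)s * Lp2 + pad);
    for (int j = 0; j < L; ++j) {
      const float* col = yp + (arma::uword)j * F;
      for (int f = 0; f < F; ++f) {
        const double v = (double)col[f] + b[f];
        sum[f] += v;
        sumsq[f] += v * v;
      }
    }
  }
  cache->bn_mean = sum / (double)N;
  cache->bn_var = sumsq / (double)N - arma::square(cache->bn_mean);
  cache->bn_var.transform([](double v) { return v > 0.0 ? v : 0.0; });
  arma::vec invstd_d = 1.0 / arma::sqrt(cache->bn_var + eps);
  cache->invstd = arma::conv_to<arma::fvec>::from(invstd_d);
  // fused normalize + scale/shift + ReLU into dense (F, L*B) buffers
  cache->xhat.set_size(F, N);
  cache->act.set_size(F, N);
  {
    std::vector<float> mu(F), is(F), ga(F), be(F), bf(F);
    for (int f = 0; f < F; ++f) {
      mu[f] = (float)cache->bn_mean[f];
      is[f] = (float)invstd_d[f];
      ga[f] = (float)gamma[f];
      be[f] = (float)beta[f];
      bf[f] = (float)b[f];
    }
    for (int s = 0; s < B; ++s) {
      const float* yp = yslab.colptr((arma::uword)s * Lp2 + pad);
      float* xh = cache->xhat.colptr((arma::uword)s * L);
      float* ap = cache->act.colptr((arma::uword)s * L);
      const arma::uword n = (arma::uword)F * L;
      for (arma::uword i = 0; i < n; ++i) {
        const int f = i % F;
        const float z = (yp[i] + bf[f] - mu[f]) * is[f];
        xh[i] = z;
        const float a = ga[f] * z + be[f];
        ap[i] = a > 0.0f ? a : 0.0f;
      }
    }
  }
  // max-pool
  cache->pooled = (pool_size > 1 || pool_stride > 1);
  const int Lp = cache->pooled ? (L + pool_stride - 1) / pool_stride : L;
  arma::fmat out;
  if (cache->pooled) {
    out.set_size(F, (arma::uword)Lp * B);
    cache->pool_idx.set_size(F, (arma::uword)Lp * B);
    for (int s = 0; s < B; ++s) {
      const float* ap = cache->act.colptr((arma::uword)s * L);
      for (int j = 0; j < Lp; ++j) {
        float* op = out.colptr((arma::uword)s * Lp + j);
        arma::uword* ip = cache->pool_idx.colptr((arma::uword)s * Lp + j);
        const int w0 = j * pool_stride;
        const int w1 = std::min(w0 + pool_size, L);
        for (int f = 0; f < F; ++f) {
          float best = ap[(arma::uword)w0 * F + f];
          int besti = w0;
          for (int t = w0 + 1; t < w1; ++t) {
            const float v = ap[(arma::uword)t * F + f];
            if (v > best) { best = v; besti = t; }
          }
          op[f] = best;
          ip[f] = besti;
        }
      }
    }
  } else {
    out = cache->act;
  }
  // inverted dropout, drawing from R's RNG for reproducibility
  if (use_dropout && drop_rate > 0) {
    RNGScope scope;
    const float scale = 1.0f / (float)(1.0 - drop_rate);
    cache->mask.set_size(F, out.n_cols);
    float* mp = cache->mask.memptr();
    float* op = out.memptr();
    const arma::uword n = out.n_elem;
    for (arma::uword i = 0; i < n; ++i) {
      const float m = (unif_rand() >= drop_rate) ? scale : 0.0f;
      mp[i] = m;
      op[i] *= m;
    }
  }
  // emit as (F, Lp, B) double array
  arma::cube outc(F, Lp, B);
  {
    const float* op = out.memptr();
    double* dp = outc.memptr();
    const arma::uword n = out.n_elem;
    for (arma::uword i = 0; i < n; ++i) dp[i] = (double)op[i];
  }
  return List::create(_["out"] = outc, _["cache"] = cache);
}

// [[Rcpp::export]]
List conv_block_backward_cpp(SEXP cache_ptr, const arma::cube& dout,
                             const arma::mat& W, const arma::vec& gamma,
                             bool need_dx) {
  XPtr<ConvCache> cache(cache_ptr);
  const int F = W.n_rows;
  const int C = cache->C, K = cache->K, pad = cache->pad;
  const int L = cache->L, B = cache->B;
  const int Lp2 = L + 2 * pad;
  const arma::uword N = (arma::uword)L * B;
  // dropout mask + unpool -> gradient at the ReLU output (F, L*B)
  arma::fmat dact(F, N, arma::fill::zeros);
  {
    const double* dp = dout.memptr();
    const bool has_mask = cache->mask.n_elem > 0;
    const float* mp = cache->mask.memptr();
    if (cache->pooled) {
      const int Lp = dout.n_cols;
      for (int s = 0; s < B; ++s) {
        float* da = dact.colptr((arma::uword)s * L);
        const double* dg = dp + (arma::uword)s * F * Lp;
        const arma::uword* ip =
          cache->pool_idx.colptr((arma::uword)s * Lp);
        const float* mg = has_mask ?
          mp + (arma::uword)s * F * Lp : nullptr;
        const arma::uword n = (arma::uword)F * Lp;
        for (arma::uword i = 0; i < n; ++i) {
          float g = (float)dg[i];
          if (has_mask) g *= mg[i];
          const int f = i % F;
          da[ip[i] * F + f] += g;
        }
      }
    } else {
      const arma::uword n = N * F;
      float* da = dact.memptr();
      for (arma::uword i = 0; i < n; ++i) {
        float g = (float)dp[i];
        if (has_mask) g *= mp[i];
        da[i] = g;
      }
    }
  }
  // ReLU mask + BN backward reductions (double accumulators)
  arma::vec dbeta(F, arma::fill::zeros), dgamma(F, arma::fill::zeros);
  {
    float* da = dact.memptr();
    const float* ap = cache->act.memptr();
    const float* xh = cache->xhat.memptr();
    const arma::uword n = N * F;
    for (arma::uword i = 0; i < n; ++i) {
      const float g = (ap[i] > 0.0f) ? da[i] : 0.0f;
      da[i] = g;
      const int f = i % F;
      dbeta[f] += g;
      dgamma[f] += (double)g * xh[i];
    }
  }
  // dz = gamma*invstd/N * (N*dact - dbeta - xhat*dgamma), zero-padded
  // into a slab for the conv GEMMs
  arma::fmat dzp(F, (arma::uword)Lp2 * B, arma::fill::zeros);
  {
    std::vector<float> sc(F), dbf(F), dgf(F);
    for (int f = 0; f < F; ++f) {
      sc[f] = (float)(gamma[f] * (double)cache->invstd[f] / (double)N);
      dbf[f] = (float)dbeta[f];
      dgf[f] = (float)dgamma[f];
    }
    const float Nf = (float)N;
    for (int s = 0; s < B; ++s) {
      const float* da = dact.colptr((arma::uword)s * L);
      const float* xh = cache->xhat.colptr((arma::uword)s * L);
      float* dz = dzp.colptr((arma::uword)s * Lp2 + pad);
      const arma::uword n = (arma::uword)F * L;
      for (arma::uword i = 0; i < n; ++i) {
        const int f = i % F;
        dz[i] = sc[f] * (Nf * da[i] - dbf[f] - xh[i] * dgf[f]);
      }
    }
  }
  // dW_k = dz_interior * xp(shifted)^T ; db = rowsum(dz)
  arma::fmat dWf(F, (arma::uword)C * K, arma::fill::zeros);
  const arma::uword ncol = dzp.n_cols;
  const arma::uword nint = ncol - 2 * pad;
  if (cache->onehot) {
    for (arma::uword g = 0; g < nint; ++g) {
      const float* dz = dzp.colptr(g + pad);
      for (int k = 0; k < K; ++k) {
        const uint16_t c = cache->idx[g + k];
        if (c >= C) continue;
        float* wp = dWf.colptr((arma::uword)k * C + c);
        for (int f = 0; f < F; ++f) wp[f] += dz[f];
      }
    }
  } else {
    const arma::fmat dzv(const_cast<float*>(dzp.colptr(pad)), F, nint,
                         false, true);
    for (int k = 0; k < K; ++k) {
      const arma::fmat xv(const_cast<float*>(cache->xp.colptr(k)), C,
                          nint, false, true);
      arma::fmat dWk(dWf.colptr((arma::uword)k * C), F, C, false, true);
      dWk = dzv * xv.t();
    }
  }
  arma::vec db(F, arma::fill::zeros);
  {
    const float* dz = dzp.memptr();
    const arma::uword n = dzp.n_elem;
    for (arma::uword i = 0; i < n; ++i) db[i % F] += dz[i];
  }
  List out = List::create(
    _["dW"] = arma::conv_to<arma::mat>::from(dWf), _["db"] = db,
    _["dgamma"] = dgamma, _["dbeta"] = dbeta,
    _["bn_mean"] = cache->bn_mean, _["bn_var"] = cache->bn_var);
  if (need_dx) {
    arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
    arma::fmat dxp(C, ncol, arma::fill::zeros);
    const arma::fmat dzv(const_cast<float*>(dzp.colptr(pad)), F, nint,
                         false, true);
    for (int k = 0; k < K; ++k) {
      const arma::fmat Wk(const_cast<float*>(Wf.colptr((arma::uword)k * C)),
                          F, C, false, true);
      arma::fmat dxv(dxp.colptr(k), C, nint, false, true);
      dxv += Wk.t() * dzv;
    }
    arma::cube dx(C, L, B);
    for (int s = 0; s < B; ++s) {
      const float* sp = dxp.colptr((arma::uword)s * Lp2 + pad);
      double* dp = dx.memptr() + (arma::uword)s * C * L;
      const arma::uword n = (arma::uword)C * L;
      for (arma::uword i = 0; i < n; ++i) dp[i] = (double)sp[i];
    }
    out["dx"] = dx;
  }
  return out;
}

// Evaluation-mode fused block: conv -> BN (running stats) -> ReLU ->
// max-pool, no dropout, no cache.
// [[Rcpp::export]]
arma::cube conv_block_eval_cpp(const arma::cube& x, const arma::mat& W,
                               const arma::vec& b, const arma::vec& gamma,
                               const arma::vec& beta,
                               const arma::vec& rmean,
                               const arma::vec& rvar, double eps,
                               int pool_size, int pool_stride) {
  const int C = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int F = W.n_rows;
  const int K = W.n_cols / C;
  const int pad = (K - 1) / 2;
  const int Lp2 = L + 2 * pad;
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
  arma::fmat yslab;
  std::vector<uint16_t> idx;
  if (slab_onehot_idx(x, pad, idx)) {
    conv_slab_onehot(Wf, idx, C, K, pad, F,
                     (arma::uword)Lp2 * B, yslab);
  } else {
    arma::fmat xp;
    make_slab(x, pad, xp);
    conv_slab(Wf, xp, C, K, pad, yslab);
  }
  arma::vec g_d = gamma / arma::sqrt(rvar + eps);
  arma::vec off_d = beta + g_d % (b - rmean);
  std::vector<float> g(F), off(F);
  for (int f = 0; f < F; ++f) {
    g[f] = (float)g_d[f];
    off[f] = (float)off_d[f];
  }
  const bool pooled = (pool_size > 1 || pool_stride > 1);
  const int Lp = pooled ? (L + pool_stride - 1) / pool_stride : L;
  arma::cube outc(F, Lp, B);
  std::vector<float> act((arma::uword)F * L);
  for (int s = 0; s < B; ++s) {
    const float* yp = yslab.colptr((arma::uword)s * Lp2 + pad);
    const arma::uword n = (arma::uword)F * L;
    for (arma::uword i = 0; i < n; ++i) {
      const int f = i % F;
      const float a = g[f] * yp[i] + off[f];
      act[i] = a > 0.0f ? a : 0.0f;
    }
    double* op = outc.memptr() + (arma::uword)s * F * Lp;
    if (!pooled) {
      for (arma::uword i = 0; i < n; ++i) op[i] = (double)act[i];
    } else {
      for (int j = 0; j < Lp; ++j) {
        const int w0 = j * pool_stride;
        const int w1 = std::min(w0 + pool_size, L);
        for (int f = 0; f < F; ++f) {
          float best = act[(arma::uword)w0 * F + f];
          for (int t = w0 + 1; t < w1; ++t) {
            const float v = act[(arma::uword)t * F + f];
            if (v > best) best = v;
          }
          op[(arma::uword)j * F + f] = (double)best;
        }
      }
    }
  }
  return outc;
}
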