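// Low-level numerical kernels for 1-D CNNs on one-hot DNA.
//
// Layout convention: a batch of sequences is an arma::cube with
// dimensions (channels/filters, length, batch). Cube memory is
// column-major slice-by-slice, so a (F, L, B) cube aliases an
// F x (L*B) matrix whose columns are ordered (slice, position) —
// exploited below to vectorize batch-norm and the GEMM reshapes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Cross-correlation ("conv") with zero padding. W is (F, C*K) with the
// channel index fastest (column c + k*C corresponds to channel c, tap k).
// Output length equals input length when pad_l = (K-1)/2 and K is odd.
// [[Rcpp::export]]
List conv1d_forward_cpp(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, int K, int pad_l,
                        bool keep_xcol) {
  const int C = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int F = W.n_rows;
  const int Lout = L;  // same padding, stride 1
  arma::mat xcol(C * K, (arma::uword)Lout * B, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    const arma::mat& xs = x.slice(s);
    for (int j = 0; j < Lout; ++j) {
      double* cp = xcol.colptr((arma::uword)s * Lout + j);
      const int start = j - pad_l;
      for (int k = 0; k < K; ++k) {
        const int pos = start + k;
        if (pos >= 0 && pos < L)
          std::memcpy(cp + (arma::uword)k * C, xs.colptr(pos),
                      C * sizeof(double));
      }
    }
  }
  arma::mat ymat = W * xcol;
  ymat.each_col() += b;
  arma::cube y(F, Lout, B);
  std::memcpy(y.memptr(), ymat.memptr(), ymat.n_elem * sizeof(double));
  List out = List::create(_["y"] = y);
  if (keep_xcol) out["xcol"] = xcol;
  return out;
}

// [[Rcpp::export]]
List conv1d_backward_cpp(const arma::cube& dy, const arma::mat& W,
                         const arma::mat& xcol, int C, int K, int L_in,
                         int pad_l) {
  const int F = dy.n_rows, Lout = dy.n_cols, B = dy.n_slices;
  const arma::mat dymat(const_cast<double*>(dy.memptr()), F,
                        (arma::uword)Lout * B, false, true);
  arma::mat dW = dymat * xcol.t();
  arma::vec db = arma::sum(dymat, 1);
  arma::mat dxcol = W.t() * dymat;  // (C*K) x (Lout*B)
  arma::cube dx(C, L_in, B, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    arma::mat& dxs = dx.slice(s);
    for (int j = 0; j < Lout; ++j) {
      const double* cp = dxcol.colptr((arma::uword)s * Lout + j);
      const int start = j - pad_l;
      for (int k = 0; k < K; ++k) {
        const int pos = start + k;
        if (pos >= 0 && pos < L_in) {
          double* tp = dxs.colptr(pos);
          const double* sp = cp + (arma::uword)k * C;
          for (int c = 0; c < C; ++c) tp[c] += sp[c];
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Max-pooling with window `p`, stride `s`; windows clipped at the right
// edge (minimal implicit right padding). Leftmost position wins ties.
// Output length is ceil(L / s).
// [[Rcpp::export]]
List maxpool_forward_cpp(const arma::cube& x, int p, int s) {
  const int F = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int Lp = (L + s - 1) / s;
  arma::cube y(F, Lp, B);
  arma::ucube idx(F, Lp, B);
  for (int bi = 0; bi < B; ++bi) {
    const arma::mat& xs = x.slice(bi);
    arma::mat& ys = y.slice(bi);
    arma::ucube::slice_iterator it = idx.begin_slice(bi);
    for (int j = 0; j < Lp; ++j) {
      const int w0 = j * s;
      const int w1 = std::min(w0 + p, L);
      for (int f = 0; f < F; ++f) {
        double best = xs(f, w0);
        int besti = w0;
        for (int t = w0 + 1; t < w1; ++t) {
          const double v = xs(f, t);
          if (v > best) { best = v; besti = t; }
        }
        ys(f, j) = best;
        idx(f, j, bi) = besti;
      }
    }
    (void)it;
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool_backward_cpp(const arma::cube& dy, const arma::ucube& idx,
                                int L_in) {
  const int F = dy.n_rows, Lp = dy.n_cols, B = dy.n_slices;
  arma::cube dx(F, L_in, B, arma::fill::zeros);
  for (int bi = 0; bi < B; ++bi)
    for (int j = 0; j < Lp; ++j)
      for (int f = 0; f < F; ++f)
        dx(f, idx(f, j, bi), bi) += dy(f, j, bi);
  return dx;
}

// Batch norm over (length, batch) per filter, biased variance.
// [[Rcpp::export]]
List bn_forward_train_cpp(const arma::cube& x, const arma::vec& gamma,
                          const arma::vec& beta, double eps) {
  const int F = x.n_rows;
  const arma::uword N = (arma::uword)x.n_cols * x.n_slices;
  const arma::mat xv(const_cast<double*>(x.memptr()), F, N, false, true);
  arma::vec mu = arma::mean(xv, 1);
  arma::mat cent = xv;
  cent.each_col() -= mu;
  arma::vec var = arma::sum(arma::square(cent), 1) / (double)N;
  arma::vec invstd = 1.0 / arma::sqrt(var + eps);
  cent.each_col() %= invstd;  // now xhat
  arma::mat ymat = cent;
  ymat.each_col() %= gamma;
  ymat.each_col() += beta;
  arma::cube y(x.n_rows, x.n_cols, x.n_slices);
  std::memcpy(y.memptr(), ymat.memptr(), ymat.n_elem * sizeof(double));
  arma::cube xhat(x.n_rows, x.n_cols, x.n_slices);
  std::memcpy(xhat.memptr(), cent.memptr(), cent.n_elem * sizeof(double));
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mu,
                      _["var"] = var, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List bn_backward_cpp(const arma::cube& dy, const arma::cube& xhat,
                     const arma::vec& gamma, const arma::vec& invstd) {
  const int F = dy.n_rows;
  const arma::uword N = (arma::uword)dy.n_cols * dy.n_slices;
  const arma::mat dyv(const_cast<double*>(dy.memptr()), F, N, false, true);
  const arma::mat xhv(const_cast<double*>(xhat.memptr()), F, N, false, true);
  arma::vec dbeta = arma::sum(dyv, 1);
  arma::vec dgamma = arma::sum(dyv % xhv, 1);
  // dx = gamma*invstd/N * (N*dy - dbeta - xhat*dgamma)
  arma::mat dxv = dyv * (double)N;
  dxv.each_col() -= dbeta;
  arma::mat tmp = xhv;
  tmp.each_col() %= dgamma;
  dxv -= tmp;
  arma::vec scale = gamma % invstd / (double)N;
  dxv.each_col() %= scale;
  arma::cube dx(dy.n_rows, dy.n_cols, dy.n_slices);
  std::memcpy(dx.memptr(), dxv.memptr(), dxv.n_elem * sizeof(double));
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
arma::cube bn_forward_eval_cpp(const arma::cube& x, const arma::vec& gamma,
                               const arma::vec& beta, const arma::vec& mean,
                               const arma::vec& var, double eps) {
  const int F = x.n_rows;
  const arma::uword N = (arma::uword)x.n_cols * x.n_slices;
  const arma::mat xv(const_cast<double*>(x.memptr()), F, N, false, true);
  arma::vec g = gamma / arma::sqrt(var + eps);
  arma::vec off = beta - g % mean;
  arma::mat yv = xv;
  yv.each_col() %= g;
  yv.each_col() += off;
  arma::cube y(x.n_rows, x.n_cols, x.n_slices);
  std::memcpy(y.memptr(), yv.memptr(), yv.n_elem * sizeof(double));
  return y;
}

// Per (filter, sequence) maximum activation and its leftmost 0-based
// position across the length axis.
// [[Rcpp::export]]
List scan_max_cpp(const arma::cube& y) {
  const int F = y.n_rows, L = y.n_cols, B = y.n_slices;
  arma::mat mx(F, B);
  arma::imat pos(F, B);
  for (int bi = 0; bi < B; ++bi) {
    const arma::mat& ys = y.slice(bi);
    for (int f = 0; f < F; ++f) {
      double best = ys(f, 0);
      int besti = 0;
      for (int j = 1; j < L; ++j) {
        const double v = ys(f, j);
        if (v > best) { best = v; besti = j; }
      }
      mx(f, bi) = best;
      pos(f, bi) = besti;
    }
  }
  return List::create(_["max"] = mx, _["pos"] = pos);
}
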