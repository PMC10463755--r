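// Multi-head attention batch kernels. Token streams arrive as
// (B*L) x d matrices (example-major rows); heads live in contiguous
// column blocks of width d/H. Masked keys receive exactly zero weight.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List mha_core_fwd_cpp(const arma::mat& Q, const arma::mat& K,
                      const arma::mat& V, const IntegerMatrix& mask,
                      int H, int B, int Lq, int Lk) {
  const int d = Q.n_cols;
  const int dh = d / H;
  const double sc = 1.0 / std::sqrt((double)dh);
  arma::mat ctx(B * Lq, d, arma::fill::zeros);
  arma::cube A_all(Lq, Lk, H * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    std::vector<int> valid;
    valid.reserve(Lk);
    for (int k = 0; k < Lk; ++k) if (mask(b, k)) valid.push_back(k);
    for (int h = 0; h < H; ++h) {
      arma::mat Qb = Q.submat(b * Lq, h * dh, (b + 1) * Lq - 1,
                              (h + 1) * dh - 1);
      arma::mat Kb = K.submat(b * Lk, h * dh, (b + 1) * Lk - 1,
                              (h + 1) * dh - 1);
      arma::mat S = Qb * Kb.t() * sc;
      arma::mat& A = A_all.slice(b * H + h);
      for (int i = 0; i < Lq; ++i) {
        double m = -arma::datum::inf;
        for (int k : valid) m = std::max(m, S(i, k));
        double s = 0.0;
        for (int k : valid) { double e = std::exp(S(i, k) - m); A(i, k) = e; s += e; }
        for (int k : valid) A(i, k) /= s;
      }
      ctx.submat(b * Lq, h * dh, (b + 1) * Lq - 1, (h + 1) * dh - 1) =
        A * V.submat(b * Lk, h * dh, (b + 1) * Lk - 1, (h + 1) * dh - 1);
    }
  }
  return List::create(_["ctx"] = ctx, _["A"] = A_all);
}

// [[Rcpp::export]]
List mha_core_bwd_cpp(const arma::mat& dctx, const arma::mat& Q,
                      const arma::mat& K, const arma::mat& V,
                      const arma::cube& A_all, int H, int B, int Lq,
                      int Lk) {
  const int d = Q.n_cols;
  const int dh = d / H;
  const double sc = 1.0 / std::sqrt((double)dh);
  arma::mat dQ(B * Lq, d, arma::fill::zeros);
  arma::mat dK(B * Lk, d, arma::fill::zeros);
  arma::mat dV(B * Lk, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < H; ++h) {
      const arma::mat& A = A_all.slice(b * H + h);
      arma::mat dc = dctx.submat(b * Lq, h * dh, (b + 1) * Lq - 1,
                                 (h + 1) * dh - 1);
      arma::mat Vb = V.submat(b * Lk, h * dh, (b + 1) * Lk - 1,
                              (h + 1) * dh - 1);
      arma::mat dA = dc * Vb.t();
      dV.submat(b * Lk, h * dh, (b + 1) * Lk - 1, (h + 1) * dh - 1) =
        A.t() * dc;
      arma::vec rs = arma::sum(dA % A, 1);
      arma::mat dS = A % (dA.each_col() - rs);
      dQ.submat(b * Lq, h * dh, (b + 1) * Lq - 1, (h + 1) * dh - 1) =
        dS * K.submat(b * Lk, h * dh, (b + 1) * Lk - 1, (h + 1) * dh - 1) * sc;
      dK.submat(b * Lk, h * dh, (b + 1) * Lk - 1, (h + 1) * dh - 1) =
        dS.t() * Q.submat(b * Lq, h * dh, (b + 1) * Lq - 1,
                          (h + 1) * dh - 1) * sc;
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}

// Gather patch columns for convolution: x is (B*P) x Cin, idx (P x K)
// holds 1-based within-image source positions (0 = zero padding).
// Output: (B*P) x (K*Cin), channel fastest within each offset block.
// [[Rcpp::export]]
arma::mat conv_im2col_cpp(const arma::mat& x, const IntegerMatrix& idx,
                          int B) {
  const int P = idx.nrow();
  const int K = idx.ncol();
  const int Cin = x.n_cols;
  arma::mat cols(B * P, K * Cin, arma::fill::zeros);
  for (int o = 0; o < K; ++o) {
    for (int b = 0; b < B; ++b) {
      const int base = b * P;
      for (int pos = 0; pos < P; ++pos) {
        const int src = idx(pos, o);
        if (src > 0) {
          const int r = base + pos;
          const int s = base + src - 1;
          for (int c = 0; c < Cin; ++c) cols(r, o * Cin + c) = x(s, c);
        }
      }
    }
  }
  return cols;
}

// Scatter-add the patch-column gradient back onto the input grid.
// [[Rcpp::export]]
arma::mat conv_col2im_cpp(const arma::mat& dcols, const IntegerMatrix& idx,
                          int B, int Cin) {
  const int P = idx.nrow();
  const int K = idx.ncol();
  arma::mat dx(B * P, Cin, arma::fill::zeros);
  for (int o = 0; o < K; ++o) {
    for (int b = 0; b < B; ++b) {
      const int base = b * P;
      for (int pos = 0; pos < P; ++pos) {
        const int src = idx(pos, o);
        if (src > 0) {
          const int r = base + pos;
          const int s = base + src - 1;
          for (int c = 0; c < Cin; ++c) dx(s, c) += dcols(r, o * Cin + c);
        }
      }
    }
  }
  return dx;
}

// 2x2 max pooling; idx (Po x 4) holds the 1-based source positions of
// each output pixel. Returns the pooled map and the winning candidate
// (1..4, first tie wins) for the backward scatter.
// [[Rcpp::export]]
List pool_fwd_cpp(const arma::mat& x, const IntegerMatrix& idx, int B,
                  int P) {
  const int Po = idx.nrow();
  const int C = x.n_cols;
  arma::mat out(B * Po, C);
  arma::imat arg(B * Po, C);
  for (int b = 0; b < B; ++b) {
    for (int pos = 0; pos < Po; ++pos) {
      const int r = b * Po + pos;
      for (int c = 0; c < C; ++c) {
        double best = -arma::datum::inf; int who = 1;
        for (int k = 0; k < 4; ++k) {
          const double v = x(b * P + idx(pos, k) - 1, c);
          if (v > best) { best = v; who = k + 1; }
        }
        out(r, c) = best; arg(r, c) = who;
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
arma::mat pool_bwd_cpp(const arma::mat& dout, const arma::imat& arg,
                       const IntegerMatrix& idx, int B, int P) {
  const int Po = idx.nrow();
  const int C = dout.n_cols;
  arma::mat dx(B * P, C, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int pos = 0; pos < Po; ++pos) {
      const int r = b * Po + pos;
      for (int c = 0; c < C; ++c) {
        dx(b * P + idx(pos, arg(r, c) - 1) - 1, c) += dout(r, c);
      }
    }
  }
  return dx;
}

// In-place bias add on a freshly allocated matrix (the caller must own
// the temporary, e.g. the result of a matrix product).
// [[Rcpp::export]]
NumericMatrix add_bias_inplace(NumericMatrix m, const NumericVector& b) {
  const int n = m.nrow(), d = m.ncol();
  for (int j = 0; j < d; ++j) {
    const double bj = b[j];
    NumericMatrix::Column col = m(_, j);
    for (int i = 0; i < n; ++i) col[i] += bj;
  }
  return m;
}

// Row-wise layer normalisation with affine transform.
// [[Rcpp::export]]
List ln_fwd_cpp(const arma::mat& x, const arma::vec& g,
                const arma::vec& b, double eps) {
  const int n = x.n_rows, d = x.n_cols;
  arma::mat xhat(n, d), out(n, d);
  arma::vec inv(n);
  for (int i = 0; i < n; ++i) {
    double mu = 0;
    for (int j = 0; j < d; ++j) mu += x(i, j);
    mu /= d;
    double v = 0;
    for (int j = 0; j < d; ++j) { double c = x(i, j) - mu; v += c * c; }
    v /= d;
    const double iv = 1.0 / std::sqrt(v + eps);
    inv[i] = iv;
    for (int j = 0; j < d; ++j) {
      const double xh = (x(i, j) - mu) * iv;
      xhat(i, j) = xh;
      out(i, j) = xh * g[j] + b[j];
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export]]
List ln_bwd_cpp(const arma::mat& dout, const arma::mat& xhat,
                const arma::vec& inv, const arma::vec& g) {
  const int n = dout.n_rows, d = dout.n_cols;
  arma::mat dx(n, d);
  arma::vec dg(d, arma::fill::zeros), db(d, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double m1 = 0, m2 = 0;
    for (int j = 0; j < d; ++j) {
      const double dxh = dout(i, j) * g[j];
      m1 += dxh;
      m2 += dxh * xhat(i, j);
      dg[j] += dout(i, j) * xhat(i, j);
      db[j] += dout(i, j);
    }
    m1 /= d; m2 /= d;
    for (int j = 0; j < d; ++j) {
      const double dxh = dout(i, j) * g[j];
      dx(i, j) = (dxh - m1 - xhat(i, j) * m2) * inv[i];
    }
  }
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}

// ReLU returning the mask needed by the backward pass.
// [[Rcpp::export]]
List relu_fwd_cpp(const arma::mat& x) {
  arma::mat out = x;
  arma::umat mask(x.n_rows, x.n_cols);
  for (arma::uword k = 0; k < x.n_elem; ++k) {
    const bool pos = x[k] > 0;
    mask[k] = pos;
    if (!pos) out[k] = 0;
  }
  return List::create(_["out"] = out, _["mask"] = mask);
}
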