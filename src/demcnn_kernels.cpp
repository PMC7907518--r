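// Fused elementwise kernels for the DemCNN hot path. Convolutions are BLAS
// matrix products on the R side; these kernels fuse the per-block
// ReLU -> batch-norm -> dropout arithmetic (and its backward) into single
// passes over the activation matrices, which would otherwise cost many
// full-matrix temporaries in R. Activations are C x N matrices (channels as
// rows, batch positions as columns).

#include <Rcpp.h>
using namespace Rcpp;

// Forward for one block given the conv output Z (C x N): ReLU, batch
// statistics over columns per row, normalization, scale/shift, inverted
// dropout (training only; draws from the R RNG so runs remain reproducible
// under set.seed). Returns the block output plus the caches the backward
// pass needs. When `training` is false, `rmean`/`rvar` are used instead of
// batch statistics; when `calibrate` is true, batch statistics are computed
// (dropout off) and returned so the caller can store them as population
// values.
// [[Rcpp::export(name = ".k_fwd_block")]]
List k_fwd_block(NumericMatrix Z, NumericVector gamma, NumericVector beta,
                 NumericVector rmean, NumericVector rvar, double eps,
                 double dropout, bool training, bool calibrate,
                 bool keep_cache) {
  const int C = Z.nrow(), N = Z.ncol();
  NumericVector mu(C), var(C);
  if (training || calibrate) {
    std::vector<double> s(C, 0.0), ss(C, 0.0);
    const double *z = Z.begin();
    for (int j = 0; j < N; ++j) {
      const double *col = z + (size_t)j * C;
      for (int i = 0; i < C; ++i) {
        double h = col[i] > 0 ? col[i] : 0.0;
        s[i] += h;
        ss[i] += h * h;
      }
    }
    for (int i = 0; i < C; ++i) {
      mu[i] = s[i] / N;
      var[i] = ss[i] / N - mu[i] * mu[i];
      if (var[i] < 0) var[i] = 0;  // guard rounding
    }
  } else {
    mu = clone(rmean);
    var = clone(rvar);
  }
  NumericVector invstd(C);
  for (int i = 0; i < C; ++i) invstd[i] = 1.0 / std::sqrt(var[i] + eps);

  NumericMatrix out(C, N);
  NumericMatrix xhat = keep_cache ? NumericMatrix(C, N) : NumericMatrix(0, 0);
  NumericMatrix mask(0, 0);
  const bool do_dropout = training && !calibrate && dropout > 0;
  if (do_dropout) mask = NumericMatrix(C, N);
  const double keep_p = 1.0 - dropout;

  if (do_dropout) GetRNGstate();
  const double *z = Z.begin();
  double *o = out.begin();
  double *xh = keep_cache ? xhat.begin() : nullptr;
  double *mk = do_dropout ? mask.begin() : nullptr;
  for (int j = 0; j < N; ++j) {
    const size_t off = (size_t)j * C;
    for (int i = 0; i < C; ++i) {
      double h = z[off + i] > 0 ? z[off + i] : 0.0;
      double x = (h - mu[i]) * invstd[i];
      if (xh) xh[off + i] = x;
      double v = x * gamma[i] + beta[i];
      if (mk) {
        double m = (unif_rand() < keep_p) ? 1.0 / keep_p : 0.0;
        mk[off + i] = m;
        v *= m;
      }
      o[off + i] = v;
    }
  }
  if (do_dropout) PutRNGstate();

  return List::create(_["out"] = out, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["invstd"] = invstd,
                      _["mask"] = mask);
}

// Backward through dropout, batch norm and ReLU for one block. dOut is the
// gradient w.r.t. the block output; xhat/mu/invstd/mask are the forward
// caches. Returns dZ (gradient w.r.t. the conv output) and the per-channel
// gamma/beta gradients. The ReLU mask is recovered from xhat: the
// pre-normalization activation h = xhat/invstd + mu is positive iff
// xhat > -mu * invstd.
// [[Rcpp::export(name = ".k_bwd_block")]]
List k_bwd_block(NumericMatrix dOut, NumericMatrix xhat,
                 NumericVector gamma, NumericVector mu,
                 NumericVector invstd, NumericMatrix mask) {
  const int C = dOut.nrow(), N = dOut.ncol();
  const bool has_mask = mask.nrow() == C;
  NumericVector dgamma(C), dbeta(C), thresh(C);
  for (int i = 0; i < C; ++i) thresh[i] = -mu[i] * invstd[i];

  NumericMatrix dZ(C, N);
  const double *dout = dOut.begin(), *xh = xhat.begin(),
               *mk = has_mask ? mask.begin() : nullptr;
  double *dz = dZ.begin();
  // pass 1: dA = dOut * mask; accumulate dgamma, dbeta; stash dA in dZ
  for (int j = 0; j < N; ++j) {
    const size_t off = (size_t)j * C;
    for (int i = 0; i < C; ++i) {
      double da = mk ? dout[off + i] * mk[off + i] : dout[off + i];
      dz[off + i] = da;
      dgamma[i] += da * xh[off + i];
      dbeta[i] += da;
    }
  }
  // batch-norm backward row constants: s1 = mean(dxhat), s2 = mean(dxhat*xhat)
  NumericVector s1(C), s2(C);
  for (int i = 0; i < C; ++i) {
    s1[i] = gamma[i] * dbeta[i] / N;
    s2[i] = gamma[i] * dgamma[i] / N;
  }
  // pass 2: dZ = ((gamma*dA - s1 - xhat*s2) * invstd) * [h > 0]
  for (int j = 0; j < N; ++j) {
    const size_t off = (size_t)j * C;
    for (int i = 0; i < C; ++i) {
      double x = xh[off + i];
      if (x > thresh[i]) {
        dz[off + i] = (gamma[i] * dz[off + i] - s1[i] - x * s2[i]) *
          invstd[i];
      } else {
        dz[off + i] = 0.0;
      }
    }
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// col2im scatter-add: fold the (K*C) x (B*P) im2col gradient back onto the
// C x (B*L) input layout. Row (c-1)K + k of dXcol holds channel c, kernel
// tap k; column (b-1)P + p maps to input column (b-1)L + (p-1)S + k.
// [[Rcpp::export(name = ".k_col2im")]]
NumericMatrix k_col2im(NumericMatrix dXcol, int C, int K, int L, int B,
                       int P, int S) {
  NumericMatrix dA(C, (size_t)B * L);
  const double *src = dXcol.begin();
  double *dst = dA.begin();
  const int KC = K * C;
  for (int b = 0; b < B; ++b) {
    for (int p = 0; p < P; ++p) {
      const size_t col_in = (size_t)b * P + p;
      const double *scol = src + col_in * KC;
      const size_t base = (size_t)b * L + (size_t)p * S;
      for (int c = 0; c < C; ++c) {
        const double *sc = scol + (size_t)c * K;
        double *dcol = dst + base * C + c;
        for (int k = 0; k < K; ++k) {
          dcol[(size_t)k * C] += sc[k];
        }
      }
    }
  }
  return dA;
}
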