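// Compiled front half of the multi-kernel conv front-end:
//   per-branch temporal conv (same padding, no bias)
//   -> per-map batch norm
//   -> grouped squeeze-and-excitation gates (residual: y * (1 + a))
//   -> depthwise spatial conv over the EEG-channel axis (valid, multiplier D)
//   -> batch norm -> ELU -> average pool P1
//
// These stages touch T x C x F1 x |K_c| activations and dominate the training
// cost, so they run here in single precision with BLAS gemms; everything
// after the first pooling stage is small (T/P1 tokens) and stays in R
// doubles. Batch norm and the SE gates are per-(map, trial) affine maps, so
// the normalized/gated tensor is never materialized: the affine folds into
// the depthwise contraction. The R reference path (backend = "R") implements
// identical arithmetic in double precision and serves as the oracle for this
// code in the test suite.
//
// Layouts (0-based):
//   X     : (T)    x (C*B)  input, column c + C*b
//   xbuf  : (T*B)  x (C*M)  conv outputs, column c + C*m, row t + T*b
//   dwout : (T*B)  x (D*M)  depthwise outputs, column d + D*m
//   out   : (T1*B) x (D*M)  pooled outputs, T1 = floor(T/P1)
// where M = n_branches * F1 maps, branch j owning maps [j*F1, (j+1)*F1).

#include <RcppArmadillo.h>
#include <chrono>
#define TCF_NOW() std::chrono::steady_clock::now()
#define TCF_SEC(a,b) std::chrono::duration<double>(b-a).count()
// [[Rcpp::depends(RcppArmadillo)]]

#if defined(__GLIBC__)
#include <malloc.h>
// The activation buffers are ~100 MB per minibatch; with glibc defaults they
// are mmap'd and returned to the OS on every free, so each training step pays
// the page-fault cost again. Raising the mmap threshold keeps them on the
// heap for reuse.
static const bool tcf_malloc_tuned = []() {
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 29);
  return true;
}();
#endif

using namespace Rcpp;

struct FeCache {
  arma::fmat xinput;   // raw input (T x C*B), for conv weight grads
  arma::fmat x;        // conv outputs (pre-BN)
  arma::fmat dwout;    // depthwise outputs (pre-BN2)
  arma::mat s;         // M x B squeeze means of the normalized maps
  arma::mat h1;        // (h*G) x B SE hidden activations
  arma::mat a;         // G x B gates
  arma::vec mu, sinv;  // per-map stage-1 BN statistics used in this pass
  arma::vec mu2, sinv2;// per-column stage-2 BN statistics
  arma::vec gamma, beta, gamma2, beta2;
  std::vector<arma::mat> Wt;
  std::vector<arma::mat> seW1, seW2;
  std::vector<arma::vec> seB1, seB2;
  arma::cube Wd;       // C x D x M
  int T, C, B, M, F1, D, G, h, P1;
  bool train;
};

static inline int pad_left(int K) { return (K - 1) / 2; }

// double-accumulator float reductions (no temporaries, vectorizable)
static inline double dsumf(const float* p, size_t n) {
  double s0 = 0, s1 = 0, s2 = 0, s3 = 0;
  size_t i = 0;
  for (; i + 4 <= n; i += 4) {
    s0 += p[i]; s1 += p[i + 1]; s2 += p[i + 2]; s3 += p[i + 3];
  }
  for (; i < n; ++i) s0 += p[i];
  return s0 + s1 + s2 + s3;
}

static inline double ddotf(const float* a, const float* b, size_t n) {
  double s0 = 0, s1 = 0, s2 = 0, s3 = 0;
  size_t i = 0;
  for (; i + 4 <= n; i += 4) {
    s0 += (double)a[i] * b[i]; s1 += (double)a[i + 1] * b[i + 1];
    s2 += (double)a[i + 2] * b[i + 2]; s3 += (double)a[i + 3] * b[i + 3];
  }
  for (; i < n; ++i) s0 += (double)a[i] * b[i];
  return s0 + s1 + s2 + s3;
}

// im2col for one EEG channel across the whole batch: col is (T*B) x K
static void build_col(arma::fmat& col, const arma::fmat& X, int T, int C,
                      int B, int c, int K) {
  const int pl = pad_left(K);
  col.zeros();
  for (int b = 0; b < B; ++b) {
    const float* src = X.colptr(c + (size_t)C * b);
    for (int k = 0; k < K; ++k) {
      int t_lo = std::max(0, pl - k);
      int t_hi = std::min(T, T + pl - k);
      if (t_hi <= t_lo) continue;
      float* dst = col.colptr(k) + (size_t)b * T;
      std::memcpy(dst + t_lo, src + (t_lo + k - pl),
                  sizeof(float) * (size_t)(t_hi - t_lo));
    }
  }
}

// per-(map,b) row gain vector of length T*B: v[t + T*b] = vals[b]
static void fill_rowvec(arma::fvec& v, const arma::vec& vals, int T, int B) {
  for (int b = 0; b < B; ++b)
    v.subvec((size_t)b * T, (size_t)b * T + T - 1).fill((float)vals[b]);
}

// [[Rcpp::export(name = ".fe_forward_cpp")]]
List fe_forward_cpp(NumericMatrix Xr, IntegerVector kernels, List WtR,
                    NumericVector gammaR, NumericVector betaR,
                    NumericVector runMeanR, NumericVector runVarR,
                    NumericVector gamma2R, NumericVector beta2R,
                    NumericVector runMean2R, NumericVector runVar2R,
                    double momentum, bool train, double eps,
                    List seW1R, List seB1R, List seW2R, List seB2R,
                    NumericVector WdR, IntegerVector dims, bool wantCache) {
  const int T = dims[0], C = dims[1], B = dims[2], F1 = dims[3], D = dims[4],
            P1 = dims[5];
  const int G = kernels.size();
  const int M = G * F1;
  const size_t n_map = (size_t)T * C * B;
  const size_t TB = (size_t)T * B;

  FeCache* cc = new FeCache();
  FeCache& cache = *cc;
  cache.T = T; cache.C = C; cache.B = B; cache.M = M; cache.F1 = F1;
  cache.D = D; cache.G = G; cache.P1 = P1; cache.train = train;

  arma::fmat Xf = arma::conv_to<arma::fmat>::from(
      arma::mat(Xr.begin(), T, (size_t)C * B, false));
  if (wantCache) cache.xinput = Xf;

  // 1. temporal convolutions, accumulating the batch-norm statistics and the
  //    per-(map, trial) squeeze sums while the conv outputs are still hot
  arma::vec mu(M), var(M);
  arma::mat xbar(M, B, arma::fill::zeros);
  cache.x.set_size(TB, (size_t)C * M);
  {
    arma::vec s1(M, arma::fill::zeros), s2(M, arma::fill::zeros);
    for (int j = 0; j < G; ++j) {
      const int K = kernels[j];
      arma::mat Wj(as<NumericMatrix>(WtR[j]).begin(), K, F1, true);
      cache.Wt.push_back(Wj);
      arma::fmat Wjf = arma::conv_to<arma::fmat>::from(Wj);
      arma::fmat col(TB, K);
      arma::fmat O;
      for (int c = 0; c < C; ++c) {
        build_col(col, Xf, T, C, B, c, K);
        O = col * Wjf;
        for (int f = 0; f < F1; ++f) {
          const int m = j * F1 + f;
          const float* oc = O.colptr(f);
          std::memcpy(cache.x.colptr(c + (size_t)C * m), oc, sizeof(float) * TB);
          s1[m] += dsumf(oc, TB);
          s2[m] += ddotf(oc, oc, TB);
          for (int b = 0; b < B; ++b)
            xbar(m, b) += dsumf(oc + (size_t)b * T, T);
        }
      }
    }
    for (int m = 0; m < M; ++m) {
      mu[m] = s1[m] / n_map;
      var[m] = std::max(0.0, s2[m] / n_map - mu[m] * mu[m]);
    }
  }
  xbar /= (double)T * C;

  NumericVector runMean = clone(runMeanR), runVar = clone(runVarR);
  arma::vec mu_use(M), sinv(M);
  if (train) {
    double unb = n_map > 1 ? (double)n_map / (n_map - 1) : 1.0;
    for (int m = 0; m < M; ++m) {
      runMean[m] = (1 - momentum) * runMean[m] + momentum * mu[m];
      runVar[m] = (1 - momentum) * runVar[m] + momentum * var[m] * unb;
      mu_use[m] = mu[m];
      sinv[m] = 1.0 / std::sqrt(var[m] + eps);
    }
  } else {
    for (int m = 0; m < M; ++m) {
      mu_use[m] = runMeanR[m];
      sinv[m] = 1.0 / std::sqrt(runVarR[m] + eps);
    }
  }
  cache.mu = mu_use; cache.sinv = sinv;
  cache.gamma = arma::vec(gammaR.begin(), M, true);
  cache.beta = arma::vec(betaR.begin(), M, true);

  // 3. squeeze of the normalized maps, grouped excitation
  cache.s.set_size(M, B);
  for (int m = 0; m < M; ++m)
    for (int b = 0; b < B; ++b)
      cache.s(m, b) = (xbar(m, b) - mu_use[m]) * sinv[m] * cache.gamma[m] +
                      cache.beta[m];

  const int h = as<NumericMatrix>(seW1R[0]).ncol();
  cache.h = h;
  cache.h1.set_size((size_t)h * G, B);
  cache.a.set_size(G, B);
  for (int g = 0; g < G; ++g) {
    arma::mat W1(as<NumericMatrix>(seW1R[g]).begin(), F1, h, true);
    arma::vec b1(as<NumericVector>(seB1R[g]).begin(), h, true);
    arma::mat W2(as<NumericMatrix>(seW2R[g]).begin(), h, 1, true);
    arma::vec b2(as<NumericVector>(seB2R[g]).begin(), 1, true);
    cache.seW1.push_back(W1); cache.seB1.push_back(b1);
    cache.seW2.push_back(W2); cache.seB2.push_back(b2);
    for (int b = 0; b < B; ++b) {
      arma::vec sg = cache.s.submat(g * F1, b, (g + 1) * F1 - 1, b);
      arma::vec hg = W1.t() * sg + b1;
      hg.transform([](double v) { return v > 0 ? v : 0.0; });
      double z = arma::dot(W2.col(0), hg) + b2[0];
      cache.h1.submat(g * h, b, (g + 1) * h - 1, b) = hg;
      cache.a(g, b) = 1.0 / (1.0 + std::exp(-z));
    }
  }

  // 4. depthwise conv with the BN+SE affine folded in:
  //    se_out = scale1(m,b) * x + shift(m,b)
  cache.Wd = arma::cube(WdR.begin(), C, D, M, true);
  cache.dwout.set_size(TB, (size_t)D * M);
  {
    arma::fmat tmp(TB, C);
    arma::fvec srow(TB);
    arma::vec vals(B);
    for (int m = 0; m < M; ++m) {
      const int g = m / F1;
      arma::fmat Wdm = arma::conv_to<arma::fmat>::from(cache.Wd.slice(m));
      for (int b = 0; b < B; ++b)
        vals[b] = cache.gamma[m] * sinv[m] * (1.0 + cache.a(g, b));
      fill_rowvec(srow, vals, T, B);
      for (int c = 0; c < C; ++c) {
        const arma::fvec xc(const_cast<float*>(cache.x.colptr(c + (size_t)C * m)),
                            TB, false);
        tmp.col(c) = xc % srow;
      }
      cache.dwout.cols((size_t)D * m, (size_t)D * m + D - 1) = tmp * Wdm;
      for (int d = 0; d < D; ++d) {
        double wsum = arma::accu(cache.Wd.slice(m).col(d));
        for (int b = 0; b < B; ++b)
          vals[b] = (cache.beta[m] - cache.gamma[m] * mu_use[m] * sinv[m]) *
                    (1.0 + cache.a(g, b)) * wsum;
        fill_rowvec(srow, vals, T, B);
        cache.dwout.col((size_t)D * m + d) += srow;
      }
    }
  }

  // 5. batch norm (per column) -> ELU -> average pool P1
  const int DM = D * M;
  arma::vec mu2(DM), var2(DM);
  NumericVector runMean2 = clone(runMean2R), runVar2 = clone(runVar2R);
  for (int q = 0; q < DM; ++q) {
    const float* oc = cache.dwout.colptr(q);
    double s1 = dsumf(oc, TB);
    double s2 = ddotf(oc, oc, TB);
    mu2[q] = s1 / TB;
    var2[q] = std::max(0.0, s2 / TB - mu2[q] * mu2[q]);
  }
  arma::vec mu2_use(DM), sinv2(DM);
  if (train) {
    double unb = TB > 1 ? (double)TB / (TB - 1) : 1.0;
    for (int q = 0; q < DM; ++q) {
      runMean2[q] = (1 - momentum) * runMean2[q] + momentum * mu2[q];
      runVar2[q] = (1 - momentum) * runVar2[q] + momentum * var2[q] * unb;
      mu2_use[q] = mu2[q];
      sinv2[q] = 1.0 / std::sqrt(var2[q] + eps);
    }
  } else {
    for (int q = 0; q < DM; ++q) {
      mu2_use[q] = runMean2R[q];
      sinv2[q] = 1.0 / std::sqrt(runVar2R[q] + eps);
    }
  }
  cache.mu2 = mu2_use; cache.sinv2 = sinv2;
  cache.gamma2 = arma::vec(gamma2R.begin(), DM, true);
  cache.beta2 = arma::vec(beta2R.begin(), DM, true);

  const int T1 = T / P1;
  NumericMatrix outR((size_t)T1 * B, DM);
  {
    arma::fvec yc(TB);
    for (int q = 0; q < DM; ++q) {
      const arma::fvec oc(const_cast<float*>(cache.dwout.colptr(q)), TB, false);
      const float sc = (float)(cache.gamma2[q] * sinv2[q]);
      const float sh = (float)(cache.beta2[q] - cache.gamma2[q] * mu2_use[q] * sinv2[q]);
      yc = oc * sc + sh;
      yc.transform([](float v) { return v > 0 ? v : std::expm1(v); });
      double* op = &outR(0, q);
      for (int b = 0; b < B; ++b) {
        const float* yp = yc.memptr() + (size_t)b * T;
        for (int t1 = 0; t1 < T1; ++t1) {
          double acc = 0;
          const float* seg = yp + (size_t)t1 * P1;
          for (int p = 0; p < P1; ++p) acc += seg[p];
          op[(size_t)b * T1 + t1] = acc / P1;
        }
      }
    }
  }

  List res = List::create(
      Named("out") = outR,
      Named("run_mean") = runMean, Named("run_var") = runVar,
      Named("run_mean2") = runMean2, Named("run_var2") = runVar2);
  if (wantCache) {
    XPtr<FeCache> ptr(cc, true);
    res["cache"] = ptr;
  } else {
    delete cc;
  }
  return res;
}

// [[Rcpp::export(name = ".fe_backward_cpp")]]
List fe_backward_cpp(SEXP cachePtr, NumericMatrix dPoolR, IntegerVector kernels) {
  XPtr<FeCache> ptr(cachePtr);
  FeCache& cache = *ptr;
  const int T = cache.T, C = cache.C, B = cache.B, M = cache.M,
            F1 = cache.F1, D = cache.D, G = cache.G, h = cache.h,
            P1 = cache.P1;
  const int DM = D * M;
  const int T1 = T / P1;
  const size_t TB = (size_t)T * B;
  const size_t n_map = (size_t)T * C * B;

  auto tA = TCF_NOW();
  // stage 5 backward: pool -> ELU -> BN2
  arma::fmat DO(TB, DM);
  NumericVector dGamma2(DM), dBeta2(DM);
  {
    arma::fvec yc(TB), dy(TB);
    for (int q = 0; q < DM; ++q) {
      // recompute BN2+ELU output for the ELU derivative
      const arma::fvec oc(const_cast<float*>(cache.dwout.colptr(q)), TB, false);
      const float sc = (float)(cache.gamma2[q] * cache.sinv2[q]);
      const float sh = (float)(cache.beta2[q] -
                               cache.gamma2[q] * cache.mu2[q] * cache.sinv2[q]);
      yc = oc * sc + sh;
      // pool backward (uniform spread, trailing samples get zero)
      dy.zeros();
      const double* dp = &dPoolR(0, q);
      for (int b = 0; b < B; ++b) {
        float* dyp = dy.memptr() + (size_t)b * T;
        for (int t1 = 0; t1 < T1; ++t1) {
          const float v = (float)(dp[(size_t)b * T1 + t1] / P1);
          float* seg = dyp + (size_t)t1 * P1;
          for (int p = 0; p < P1; ++p) seg[p] = v;
        }
      }
      // ELU backward: yc holds the pre-ELU value x, ELU'(x) = x>0 ? 1 : exp(x)
      for (size_t i = 0; i < TB; ++i) {
        const float yv = yc[i];
        if (yv <= 0) dy[i] *= std::exp(yv);
      }
      // BN2 backward reductions against xhat
      const double tot = dsumf(dy.memptr(), TB);
      const double dotx = ddotf(dy.memptr(), oc.memptr(), TB);
      const double dgam = (dotx - cache.mu2[q] * tot) * cache.sinv2[q];
      dGamma2[q] = dgam; dBeta2[q] = tot;
      const double g1 = cache.gamma2[q] * cache.sinv2[q];
      if (cache.train) {
        const double mb = tot / TB, mg = dgam / TB;
        const float c1 = (float)g1;
        const float c2 = (float)(-g1 * mg * cache.sinv2[q]);
        const float c3 = (float)(-g1 * (mb - mg * cache.mu2[q] * cache.sinv2[q]));
        DO.col(q) = dy * c1 + oc * c2 + c3;
      } else {
        DO.col(q) = dy * (float)g1;
      }
    }
  }

  arma::fmat DS(TB, (size_t)C * M);
  arma::cube dWd(C, D, M, arma::fill::zeros);
  arma::mat da(G, B, arma::fill::zeros);

  auto tB = TCF_NOW();
  // phase 1: depthwise backward + gate-gradient accumulation
  {
    arma::fmat tmp(TB, C);
    arma::fvec srow(TB);
    arma::vec vals(B);
    for (int m = 0; m < M; ++m) {
      const int g = m / F1;
      arma::fmat Wdm = arma::conv_to<arma::fmat>::from(cache.Wd.slice(m));
      arma::fmat DOm = DO.cols((size_t)D * m, (size_t)D * m + D - 1);

      for (int b = 0; b < B; ++b)
        vals[b] = cache.gamma[m] * cache.sinv[m] * (1.0 + cache.a(g, b));
      fill_rowvec(srow, vals, T, B);
      for (int c = 0; c < C; ++c) {
        const arma::fvec xc(const_cast<float*>(cache.x.colptr(c + (size_t)C * m)),
                            TB, false);
        tmp.col(c) = xc % srow;
      }
      dWd.slice(m) += arma::conv_to<arma::mat>::from(tmp.t() * DOm);
      for (int d = 0; d < D; ++d) {
        const float* dc = DOm.colptr(d);
        double sv = 0;
        for (int b = 0; b < B; ++b) {
          double shift = (cache.beta[m] -
                          cache.gamma[m] * cache.mu[m] * cache.sinv[m]) *
                         (1.0 + cache.a(g, b));
          sv += shift * dsumf(dc + (size_t)b * T, T);
        }
        for (int c = 0; c < C; ++c) dWd(c, d, m) += sv;
      }

      DS.cols((size_t)C * m, (size_t)C * m + C - 1) = DOm * Wdm.t();

      const double g1 = cache.gamma[m] * cache.sinv[m];
      const double g0 = cache.beta[m] - cache.gamma[m] * cache.mu[m] * cache.sinv[m];
      for (int c = 0; c < C; ++c) {
        const float* xs = cache.x.colptr(c + (size_t)C * m);
        const float* ds = DS.colptr(c + (size_t)C * m);
        for (int b = 0; b < B; ++b) {
          da(g, b) += g1 * ddotf(xs + (size_t)b * T, ds + (size_t)b * T, T) +
                      g0 * dsumf(ds + (size_t)b * T, T);
        }
      }
    }
  }

  auto tC = TCF_NOW();
  // phase 2: SE excitation backward
  List dW1(G), dB1(G), dW2(G), dB2(G);
  arma::mat dsq(M, B, arma::fill::zeros);
  for (int g = 0; g < G; ++g) {
    arma::mat dW1g(F1, h, arma::fill::zeros), dW2g(h, 1, arma::fill::zeros);
    arma::vec dB1g(h, arma::fill::zeros), dB2g(1, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      double av = cache.a(g, b);
      double dz = da(g, b) * av * (1.0 - av);
      arma::vec hg = cache.h1.submat(g * h, b, (g + 1) * h - 1, b);
      dW2g.col(0) += hg * dz;
      dB2g[0] += dz;
      arma::vec dh = cache.seW2[g].col(0) * dz;
      for (int i = 0; i < h; ++i) if (hg[i] <= 0) dh[i] = 0;
      arma::vec sg = cache.s.submat(g * F1, b, (g + 1) * F1 - 1, b);
      dW1g += sg * dh.t();
      dB1g += dh;
      dsq.submat(g * F1, b, (g + 1) * F1 - 1, b) += cache.seW1[g] * dh;
    }
    dW1[g] = wrap(dW1g); dB1[g] = wrap(dB1g);
    dW2[g] = wrap(dW2g); dB2[g] = wrap(dB2g);
  }

  auto tD = TCF_NOW();
  // phase 3: residual gate + stage-1 BN backward, in place in DS
  NumericVector dGamma(M), dBeta(M);
  {
    arma::fvec grow(TB), arow(TB);
    arma::vec vals(B);
    for (int m = 0; m < M; ++m) {
      const int g = m / F1;
      for (int b = 0; b < B; ++b) vals[b] = 1.0 + cache.a(g, b);
      fill_rowvec(grow, vals, T, B);
      for (int b = 0; b < B; ++b) vals[b] = dsq(m, b) / ((double)T * C);
      fill_rowvec(arow, vals, T, B);
      double tot = 0, dotx = 0;
      for (int c = 0; c < C; ++c) {
        arma::fvec dc(DS.colptr(c + (size_t)C * m), TB, false, true);
        const arma::fvec xc(const_cast<float*>(cache.x.colptr(c + (size_t)C * m)),
                            TB, false);
        dc = dc % grow + arow;
        tot += dsumf(dc.memptr(), TB);
        dotx += ddotf(dc.memptr(), xc.memptr(), TB);
      }
      const double dgam = (dotx - cache.mu[m] * tot) * cache.sinv[m];
      dGamma[m] = dgam; dBeta[m] = tot;
      const double g1 = cache.gamma[m] * cache.sinv[m];
      if (cache.train) {
        const double mb = tot / n_map, mg = dgam / n_map;
        const float c1 = (float)g1;
        const float c2 = (float)(-g1 * mg * cache.sinv[m]);
        const float c3 = (float)(-g1 * (mb - mg * cache.mu[m] * cache.sinv[m]));
        for (int c = 0; c < C; ++c) {
          arma::fvec dc(DS.colptr(c + (size_t)C * m), TB, false, true);
          const arma::fvec xc(const_cast<float*>(cache.x.colptr(c + (size_t)C * m)),
                              TB, false);
          dc = dc * c1 + xc * c2 + c3;
        }
      } else {
        for (int c = 0; c < C; ++c) {
          arma::fvec dc(DS.colptr(c + (size_t)C * m), TB, false, true);
          dc *= (float)g1;
        }
      }
    }
  }

  auto tE = TCF_NOW();
  // phase 4: temporal-conv weight gradients from im2col views of the cached
  // raw input (no input gradient: this is the first layer)
  List dWt(G);
  for (int j = 0; j < G; ++j) {
    const int K = kernels[j];
    arma::fmat col(TB, K);
    arma::fmat DG(TB, F1);
    arma::mat acc(K, F1, arma::fill::zeros);
    for (int c = 0; c < C; ++c) {
      build_col(col, cache.xinput, T, C, B, c, K);
      for (int f = 0; f < F1; ++f)
        std::memcpy(DG.colptr(f), DS.colptr(c + (size_t)C * (j * F1 + f)),
                    sizeof(float) * TB);
      acc += arma::conv_to<arma::mat>::from(col.t() * DG);
    }
    dWt[j] = wrap(acc);
  }

  auto tF = TCF_NOW();
  if (std::getenv("TCF_PROF")) Rprintf("bwd: s5 %.3f p1 %.3f p2 %.3f p3 %.3f p4 %.3f\n", TCF_SEC(tA,tB), TCF_SEC(tB,tC), TCF_SEC(tC,tD), TCF_SEC(tD,tE), TCF_SEC(tE,tF));
  return List::create(
      Named("dWt") = dWt, Named("dGamma") = dGamma, Named("dBeta") = dBeta,
      Named("dGamma2") = dGamma2, Named("dBeta2") = dBeta2,
      Named("dSeW1") = dW1, Named("dSeB1") = dB1,
      Named("dSeW2") = dW2, Named("dSeB2") = dB2,
      Named("dWd") = wrap(dWd));
}
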