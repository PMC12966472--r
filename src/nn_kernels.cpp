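// Low-level kernels for the encoder-decoder network: direct (shifted-GEMM)
// convolutions in single precision, batch normalisation, 2x2 max pooling
// and nearest-neighbour upsampling, with analytic backward passes. Arrays
// are R column-major [H, W, C, N]; convolution weights are [kh, kw, Cin, Cout].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Convolutions run in single precision internally: on 1-CPU hosts the
// float GEMM roughly doubles throughput, and heatmap regression is far
// from the precision floor. Inputs/outputs stay double at the R boundary.

static arma::fvec toFloat(const double* p, size_t n) {
  arma::fvec out(n);
  for (size_t i = 0; i < n; ++i) out[i] = (float)p[i];
  return out;
}

// Raw BLAS single-precision GEMM on strided submatrices: avoids the
// temporaries Armadillo subview expressions materialise in the hot loops.
extern "C" void sgemm_(const char*, const char*, const int*, const int*,
                       const int*, const float*, const float*, const int*,
                       const float*, const int*, const float*, float*,
                       const int*);

static void sgemmRaw(char ta, char tb, int m, int n, int k, float alpha,
                     const float* A, int lda, const float* B, int ldb,
                     float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

// Extract the (Cin x Cout) weight slice of one kernel tap (ki, kj) from the
// [kh, kw, Cin, Cout] layout.
static arma::fmat tapWeights(const arma::fvec& wf, int ki, int kj, int kh,
                             int kw, int Cin, int Cout) {
  arma::fmat Wk(Cin, Cout);
  const int kk = kh * kw;
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      Wk(ci, co) = wf[ki + kh * kj + kk * (ci + (size_t)Cin * co)];
  return Wk;
}

// Direct convolution: for each kernel tap, the output is a flat-shifted
// GEMM of the input against that tap's channel-mixing matrix. A flat shift
// by dy wraps rows across column boundaries, so the |dy| wrapped rows per
// column are corrected afterwards; the x-range clamp handles dx edges.
static void convTapsForward(const float* xp, arma::fmat& Y, const arma::fvec& wf,
                            int H, int W, int C, int Cout, int kh, int kw) {
  const int HW = H * W;
  const int ph = kh / 2, pw = kw / 2;
  arma::fmat X(const_cast<float*>(xp), HW, C, false);
  for (int kj = 0; kj < kw; ++kj) {
    for (int ki = 0; ki < kh; ++ki) {
      const int dy = ki - ph, dx = kj - pw;
      const int off = dy + H * dx;
      const int p0 = std::max(0, -off), p1 = HW - std::max(0, off);
      if (p1 <= p0) continue;
      arma::fmat Wk = tapWeights(wf, ki, kj, kh, kw, C, Cout);
      // Y[p0:p1, ] += X[p0+off : p1+off, ] * Wk, in place
      sgemmRaw('N', 'N', p1 - p0, Cout, C, 1.0f,
               X.memptr() + p0 + off, HW, Wk.memptr(), C, 1.0f,
               Y.memptr() + p0, HW);
      if (dy != 0) {
        // wrapped rows: gather, one small GEMM, scatter-subtract
        std::vector<int> bad;
        const int yFrom = dy > 0 ? H - dy : 0;
        const int yTo = dy > 0 ? H : -dy;
        for (int wx = 0; wx < W; ++wx)
          for (int ym = yFrom; ym < yTo; ++ym) {
            const int p = wx * H + ym;
            if (p >= p0 && p < p1) bad.push_back(p);
          }
        if (!bad.empty()) {
          arma::fmat Xb((int)bad.size(), C);
          for (size_t t = 0; t < bad.size(); ++t)
            for (int ci = 0; ci < C; ++ci)
              Xb(t, ci) = X(bad[t] + off, ci);
          arma::fmat Yb = Xb * Wk;
          for (size_t t = 0; t < bad.size(); ++t)
            for (int co = 0; co < Cout; ++co)
              Y(bad[t], co) -= Yb(t, co);
        }
      }
    }
  }
}

// Backward of the direct convolution: per-tap weight gradients and, when
// needed, the input gradient, with the same wrapped-row corrections.
static void convTapsBackward(const float* xp, const float* gp,
                             arma::fmat* dXmat, arma::fvec& dW,
                             const arma::fvec& wf, int H, int W, int C,
                             int Cout, int kh, int kw) {
  const int HW = H * W;
  const int ph = kh / 2, pw = kw / 2;
  const int kk = kh * kw;
  arma::fmat X(const_cast<float*>(xp), HW, C, false);
  arma::fmat G(const_cast<float*>(gp), HW, Cout, false);
  for (int kj = 0; kj < kw; ++kj) {
    for (int ki = 0; ki < kh; ++ki) {
      const int dy = ki - ph, dx = kj - pw;
      const int off = dy + H * dx;
      const int p0 = std::max(0, -off), p1 = HW - std::max(0, off);
      if (p1 <= p0) continue;
      arma::fmat dWk(C, Cout);
      // dWk = X[p0+off : p1+off, ]^T * G[p0:p1, ]
      sgemmRaw('T', 'N', C, Cout, p1 - p0, 1.0f,
               X.memptr() + p0 + off, HW, G.memptr() + p0, HW, 0.0f,
               dWk.memptr(), C);
      arma::fmat Wk = tapWeights(wf, ki, kj, kh, kw, C, Cout);
      if (dXmat)
        // dX[p0+off : p1+off, ] += G[p0:p1, ] * Wk^T, in place
        sgemmRaw('N', 'T', p1 - p0, C, Cout, 1.0f,
                 G.memptr() + p0, HW, Wk.memptr(), C, 1.0f,
                 dXmat->memptr() + p0 + off, HW);
      if (dy != 0) {
        std::vector<int> bad;
        const int yFrom = dy > 0 ? H - dy : 0;
        const int yTo = dy > 0 ? H : -dy;
        for (int wx = 0; wx < W; ++wx)
          for (int ym = yFrom; ym < yTo; ++ym) {
            const int p = wx * H + ym;
            if (p >= p0 && p < p1) bad.push_back(p);
          }
        if (!bad.empty()) {
          arma::fmat Xb((int)bad.size(), C), Gb((int)bad.size(), Cout);
          for (size_t t = 0; t < bad.size(); ++t) {
            for (int ci = 0; ci < C; ++ci) Xb(t, ci) = X(bad[t] + off, ci);
            for (int co = 0; co < Cout; ++co) Gb(t, co) = G(bad[t], co);
          }
          dWk -= Xb.t() * Gb;
          if (dXmat) {
            arma::fmat dXb = Gb * Wk.t();
            for (size_t t = 0; t < bad.size(); ++t)
              for (int ci = 0; ci < C; ++ci)
                (*dXmat)(bad[t] + off, ci) -= dXb(t, ci);
          }
        }
      }
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < C; ++ci)
          dW(ki + kh * kj + kk * (ci + (size_t)C * co)) += dWk(ci, co);
    }
  }
}

// [[Rcpp::export]]
NumericVector nnConvForward(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv: channel mismatch");
  const int HW = H * W, K = kh * kw * C;
  NumericVector y(R_xlen_t(HW) * Cout * N);
  arma::fvec wf = toFloat(w.begin(), w.size());
  arma::fvec xf = toFloat(x.begin(), x.size());
  arma::fmat Y(HW, Cout);
  for (int n = 0; n < N; ++n) {
    if (kh == 1 && kw == 1) {
      // 1x1 convolution is a plain channel-mixing GEMM
      arma::fmat Wm(wf.memptr(), K, Cout, false);
      arma::fmat X(xf.memptr() + (size_t)n * HW * C, HW, C, false);
      Y = X * Wm;
    } else {
      Y.zeros();
      convTapsForward(xf.memptr() + (size_t)n * HW * C, Y, wf, H, W, C,
                      Cout, kh, kw);
    }
    double* yp = y.begin() + (size_t)n * HW * Cout;
    for (int co = 0; co < Cout; ++co) {
      const float* op = Y.colptr(co);
      const double bc = b[co];
      double* yq = yp + (size_t)co * HW;
      for (int i = 0; i < HW; ++i) yq[i] = (double)op[i] + bc;
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export]]
List nnConvBackward(NumericVector x, NumericVector w, NumericVector dy,
                    bool needDx = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int HW = H * W, K = kh * kw * C;
  NumericVector dx(needDx ? R_xlen_t(HW) * C * N : 0);
  NumericVector dw(w.size()), db(Cout);
  arma::fvec wf = toFloat(w.begin(), w.size());
  arma::fvec xf = toFloat(x.begin(), x.size());
  arma::fvec gf = toFloat(dy.begin(), dy.size());
  arma::fvec dWf(w.size(), arma::fill::zeros);
  arma::fmat dWm(dWf.memptr(), K, Cout, false);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::fmat dX;
  for (int n = 0; n < N; ++n) {
    arma::fmat G(gf.memptr() + (size_t)n * HW * Cout, HW, Cout, false);
    dbv += arma::conv_to<arma::vec>::from(arma::sum(G, 0).t());
    if (kh == 1 && kw == 1) {
      arma::fmat Wm(wf.memptr(), K, Cout, false);
      arma::fmat X(xf.memptr() + (size_t)n * HW * C, HW, C, false);
      dWm += X.t() * G;
      if (needDx) {
        dX = G * Wm.t();
        double* dp = dx.begin() + (size_t)n * HW * C;
        const float* sp = dX.memptr();
        for (size_t i = 0; i < (size_t)HW * C; ++i) dp[i] = sp[i];
      }
    } else {
      if (needDx) {
        dX.zeros(HW, C);
        convTapsBackward(xf.memptr() + (size_t)n * HW * C,
                         gf.memptr() + (size_t)n * HW * Cout, &dX, dWf, wf,
                         H, W, C, Cout, kh, kw);
        double* dp = dx.begin() + (size_t)n * HW * C;
        const float* sp = dX.memptr();
        for (size_t i = 0; i < (size_t)HW * C; ++i) dp[i] = sp[i];
      } else {
        convTapsBackward(xf.memptr() + (size_t)n * HW * C,
                         gf.memptr() + (size_t)n * HW * Cout, nullptr, dWf,
                         wf, H, W, C, Cout, kh, kw);
      }
    }
  }
  for (int i = 0; i < (int)dw.size(); ++i) dw[i] = (double)dWf[i];
  dw.attr("dim") = wd;
  if (!needDx)
    return List::create(_["dx"] = R_NilValue, _["dw"] = dw, _["db"] = db);
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Batch normalisation, optionally fused with ReLU (every activation in
// the network follows a batch norm, so fusing avoids two full-size R
// allocations per layer call).
// [[Rcpp::export]]
List nnBnForward(NumericVector x, NumericVector gamma, NumericVector beta,
                 NumericVector rmean, NumericVector rvar, double momentum,
                 bool training, double eps, bool relu = false) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int HW = H * W;
  const double M = (double)HW * N;
  NumericVector y(x.size()), meanOut(C), invstdOut(C), nrm(C), nrv(C);
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + ((size_t)c + (size_t)C * n) * HW;
        for (int i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      m = s / M;
      v = s2 / M - m * m;
      if (v < 0) v = 0;
      nrm[c] = momentum * rmean[c] + (1 - momentum) * m;
      nrv[c] = momentum * rvar[c] + (1 - momentum) * v;
    } else {
      m = rmean[c];
      v = rvar[c];
      nrm[c] = rmean[c];
      nrv[c] = rvar[c];
    }
    const double istd = 1.0 / std::sqrt(v + eps);
    meanOut[c] = m;
    invstdOut[c] = istd;
    const double g = gamma[c], bb = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((size_t)c + (size_t)C * n) * HW;
      double* q = y.begin() + ((size_t)c + (size_t)C * n) * HW;
      if (relu) {
        for (int i = 0; i < HW; ++i) {
          const double v = g * (p[i] - m) * istd + bb;
          q[i] = v > 0 ? v : 0;
        }
      } else {
        for (int i = 0; i < HW; ++i) q[i] = g * (p[i] - m) * istd + bb;
      }
    }
  }
  y.attr("dim") = xd;
  return List::create(_["y"] = y, _["mean"] = meanOut,
                      _["invstd"] = invstdOut, _["rmean"] = nrm,
                      _["rvar"] = nrv);
}

// [[Rcpp::export]]
List nnBnBackward(NumericVector x, NumericVector dy, NumericVector gamma,
                  NumericVector mean, NumericVector invstd, bool training,
                  Nullable<NumericVector> reluY = R_NilValue) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int HW = H * W;
  const double M = (double)HW * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  const double* ry = reluY.isNotNull() ?
    NumericVector(reluY.get()).begin() : nullptr;
  for (int c = 0; c < C; ++c) {
    const double m = mean[c], istd = invstd[c], g = gamma[c];
    double sdy = 0, sdyx = 0;
    for (int n = 0; n < N; ++n) {
      const size_t o = ((size_t)c + (size_t)C * n) * HW;
      const double* px = x.begin() + o;
      const double* pd = dy.begin() + o;
      const double* py = ry ? ry + o : nullptr;
      for (int i = 0; i < HW; ++i) {
        const double d = (py && py[i] <= 0) ? 0 : pd[i];
        sdy += d;
        sdyx += d * (px[i] - m) * istd;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    for (int n = 0; n < N; ++n) {
      const size_t o = ((size_t)c + (size_t)C * n) * HW;
      const double* px = x.begin() + o;
      const double* pd = dy.begin() + o;
      const double* py = ry ? ry + o : nullptr;
      double* pq = dx.begin() + o;
      if (training) {
        for (int i = 0; i < HW; ++i) {
          const double d = (py && py[i] <= 0) ? 0 : pd[i];
          const double xh = (px[i] - m) * istd;
          pq[i] = g * istd * (d - sdy / M - xh * sdyx / M);
        }
      } else {
        for (int i = 0; i < HW; ++i) {
          const double d = (py && py[i] <= 0) ? 0 : pd[i];
          pq[i] = g * istd * d;
        }
      }
    }
  }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
List nnMaxPool2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool: odd spatial size");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(R_xlen_t(Ho) * Wo * C * N);
  IntegerVector arg(y.size());
  const int HW = H * W, HWo = Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)c + (size_t)C * n) * HW;
      double* q = y.begin() + ((size_t)c + (size_t)C * n) * HWo;
      int* a = arg.begin() + ((size_t)c + (size_t)C * n) * HWo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const int base = 2 * ho + H * 2 * wo;
          const int cand[4] = {base, base + 1, base + H, base + H + 1};
          int best = cand[0];
          for (int t = 1; t < 4; ++t)
            if (p[cand[t]] > p[best]) best = cand[t];
          q[ho + Ho * wo] = p[best];
          a[ho + Ho * wo] = best;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector nnMaxPool2Backward(NumericVector dy, IntegerVector argmax,
                                 IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2, HW = H * W, HWo = Ho * Wo;
  NumericVector dx(R_xlen_t(HW) * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* pd = dy.begin() + ((size_t)c + (size_t)C * n) * HWo;
      const int* a = argmax.begin() + ((size_t)c + (size_t)C * n) * HWo;
      double* q = dx.begin() + ((size_t)c + (size_t)C * n) * HW;
      for (int i = 0; i < HWo; ++i) q[a[i]] += pd[i];
    }
  dx.attr("dim") = xdim;
  return dx;
}

// [[Rcpp::export]]
NumericVector nnUpsample2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W, HW = H * W, HWo = Ho * Wo;
  NumericVector y(R_xlen_t(HWo) * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)c + (size_t)C * n) * HW;
      double* q = y.begin() + ((size_t)c + (size_t)C * n) * HWo;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = p[h + H * w];
          const int b = 2 * h + Ho * 2 * w;
          q[b] = v; q[b + 1] = v; q[b + Ho] = v; q[b + Ho + 1] = v;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector nnUpsample2Backward(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, W = Wo / 2, HW = H * W, HWo = Ho * Wo;
  NumericVector dx(R_xlen_t(HW) * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = dy.begin() + ((size_t)c + (size_t)C * n) * HWo;
      double* q = dx.begin() + ((size_t)c + (size_t)C * n) * HW;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const int b = 2 * h + Ho * 2 * w;
          q[h + H * w] = p[b] + p[b + 1] + p[b + Ho] + p[b + Ho + 1];
        }
    }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
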