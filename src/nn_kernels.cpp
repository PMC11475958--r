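// Hot loops of the 1-D network engine: patch extraction (im2col) and its
// adjoint (col2im) for convolutions, plus the in-place Adam update.
// Everything else (GEMM via BLAS, batch norm, pooling) stays in R.

#include <Rcpp.h>
using namespace Rcpp;

// x: array (B, L, C); returns P (B*Lout, K*C) with column j = c*K + k
// holding x[b, t*stride + k - pl, c] (zero outside [0, L)).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int B, int L, int C,
                         int K, int stride, int pl, int Lout) {
  NumericMatrix P(B * Lout, K * C);
  const double *px = x.begin();
  double *pp = P.begin();
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      double *col = pp + (size_t)(c * K + k) * B * Lout;
      for (int t = 0; t < Lout; ++t) {
        int l = t * stride + k - pl;
        double *dst = col + (size_t)t * B;
        if (l < 0 || l >= L) {
          for (int b = 0; b < B; ++b) dst[b] = 0.0;
        } else {
          const double *src = px + (size_t)l * B + (size_t)c * B * L;
          for (int b = 0; b < B; ++b) dst[b] = src[b];
        }
      }
    }
  }
  return P;
}

// Adjoint of cpp_im2col: scatter-add dP (B*Lout, K*C) back onto the
// input gradient array (B, L, C).
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dP, int B, int L, int C,
                         int K, int stride, int pl, int Lout) {
  NumericVector dx((size_t)B * L * C);
  double *pdx = dx.begin();
  const double *pp = dP.begin();
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      const double *col = pp + (size_t)(c * K + k) * B * Lout;
      for (int t = 0; t < Lout; ++t) {
        int l = t * stride + k - pl;
        if (l < 0 || l >= L) continue;
        double *dst = pdx + (size_t)l * B + (size_t)c * B * L;
        const double *src = col + (size_t)t * B;
        for (int b = 0; b < B; ++b) dst[b] += src[b];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(B, L, C);
  return dx;
}

// In-place Adam update with bias corrections folded into lrEff/epsEff.
// [[Rcpp::export]]
void cpp_adam(NumericVector param, NumericVector m, NumericVector v,
              NumericVector g, double beta1, double beta2,
              double lrEff, double epsEff) {
  R_xlen_t n = param.size();
  double *pp = param.begin(), *pm = m.begin(), *pv = v.begin(),
         *pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = beta1 * pm[i] + (1.0 - beta1) * pg[i];
    pv[i] = beta2 * pv[i] + (1.0 - beta2) * pg[i] * pg[i];
    pp[i] -= lrEff * pm[i] / (std::sqrt(pv[i]) + epsEff);
  }
}

// Batch-norm forward over an (n, C) matrix: returns normalized output,
// xhat, and the batch statistics.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericMatrix xm, NumericVector gamma, NumericVector beta,
                double eps) {
  int n = xm.nrow(), C = xm.ncol();
  NumericMatrix y(n, C), xhat(n, C);
  NumericVector mu(C), var(C), istd(C);
  for (int c = 0; c < C; ++c) {
    const double *col = &xm(0, c);
    double s = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s += col[i]; s2 += col[i] * col[i]; }
    double m = s / n;
    double v = s2 / n - m * m;
    if (v < 0) v = 0;
    mu[c] = m; var[c] = v;
    double is = 1.0 / std::sqrt(v + eps);
    istd[c] = is;
    double g = gamma[c], b = beta[c];
    double *py = &y(0, c), *ph = &xhat(0, c);
    for (int i = 0; i < n; ++i) {
      double h = (col[i] - m) * is;
      ph[i] = h;
      py[i] = g * h + b;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["istd"] = istd);
}

// Batch-norm backward: standard per-channel gradient.
// [[Rcpp::export]]
List cpp_bn_bwd(NumericMatrix dym, NumericMatrix xhat,
                NumericVector gamma, NumericVector istd) {
  int n = dym.nrow(), C = dym.ncol();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double *pd = &dym(0, c), *ph = &xhat(0, c);
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s1 += pd[i]; s2 += pd[i] * ph[i]; }
    dbeta[c] = s1; dgamma[c] = s2;
    double g = gamma[c], is = istd[c];
    double *px = &dx(0, c);
    double gs1 = g * s1, gs2 = g * s2;
    for (int i = 0; i < n; ++i)
      px[i] = (g * pd[i] * n - gs1 - ph[i] * gs2) * is / n;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Max pool (window 2, stride 2) over (B, L, C); drops a trailing odd
// element. Returns pooled output and the left-argmax indicator.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int B, int L, int C) {
  int Lout = L / 2;
  NumericVector y((size_t)B * Lout * C);
  LogicalVector takeA((size_t)B * Lout * C);
  const double *px = x.begin();
  double *py = y.begin();
  int *pt = takeA.begin();
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < Lout; ++t) {
      const double *a = px + (size_t)(2 * t) * B + (size_t)c * B * L;
      const double *b = a + B;
      double *dst = py + (size_t)t * B + (size_t)c * B * Lout;
      int *tk = pt + (size_t)t * B + (size_t)c * B * Lout;
      for (int i = 0; i < B; ++i) {
        bool left = a[i] >= b[i];
        tk[i] = left;
        dst[i] = left ? a[i] : b[i];
      }
    }
  y.attr("dim") = IntegerVector::create(B, Lout, C);
  return List::create(_["y"] = y, _["takeA"] = takeA);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, LogicalVector takeA,
                              int B, int L, int C) {
  int Lout = L / 2;
  NumericVector dx((size_t)B * L * C);
  const double *pd = dy.begin();
  const int *pt = takeA.begin();
  double *px = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < Lout; ++t) {
      const double *src = pd + (size_t)t * B + (size_t)c * B * Lout;
      const int *tk = pt + (size_t)t * B + (size_t)c * B * Lout;
      double *a = px + (size_t)(2 * t) * B + (size_t)c * B * L;
      double *b = a + B;
      for (int i = 0; i < B; ++i) {
        if (tk[i]) a[i] = src[i]; else b[i] = src[i];
      }
    }
  dx.attr("dim") = IntegerVector::create(B, L, C);
  return dx;
}
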