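// Fused elementwise/column-wise kernels for the hot training path: batch
// normalization, PReLU and bias addition in single memory passes.

#include <Rcpp.h>

#if defined(__x86_64__) && defined(__GNUC__) && !defined(__clang__)
#define HOT_CLONES __attribute__((target_clones("arch=haswell", "default")))
#else
#define HOT_CLONES
#endif


#include <vector>
#include <cmath>
using namespace Rcpp;

// per-column mean and biased variance in one pass
static HOT_CLONES List cpp_colstats_impl(const NumericMatrix& x) {
  const int C = x.ncol();
  const R_xlen_t n = x.nrow();
  NumericVector mu(C), va(C);
  for (int c = 0; c < C; ++c) {
    const double* col = x.begin() + (R_xlen_t)c * n;
    double s = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) { s += col[i]; s2 += col[i] * col[i]; }
    const double m = s / n;
    mu[c] = m;
    va[c] = s2 / n - m * m;
    if (va[c] < 0) va[c] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// y = x * a[col] + b[col] in one pass (batch-norm affine, bias add, ...)
static HOT_CLONES NumericMatrix cpp_affine_cols_impl(const NumericMatrix& x, const NumericVector& a,
                              const NumericVector& b) {
  const int C = x.ncol();
  const R_xlen_t n = x.nrow();
  NumericMatrix y(n, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (R_xlen_t)c * n;
    double* yc = y.begin() + (R_xlen_t)c * n;
    const double ac = a[c], bc = b[c];
    for (R_xlen_t i = 0; i < n; ++i) yc[i] = xc[i] * ac + bc;
  }
  return y;
}

// batch-norm input gradient with batch statistics:
// dx = istd * (g*gamma - mean_col(g*gamma) - xh * mean_col(g*gamma * xh)),
// xh = (x - mu) * istd; also returns dgamma = sum(g*xh), dbeta = sum(g)
static HOT_CLONES List cpp_bn_bwd_impl(const NumericMatrix& g, const NumericMatrix& x,
                const NumericVector& gamma, const NumericVector& mu,
                const NumericVector& istd, bool training) {
  const int C = g.ncol();
  const R_xlen_t n = g.nrow();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* gc = g.begin() + (R_xlen_t)c * n;
    const double* xc = x.begin() + (R_xlen_t)c * n;
    double* dc = dx.begin() + (R_xlen_t)c * n;
    const double m = mu[c], is = istd[c], ga = gamma[c];
    double sg = 0.0, sgx = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double xh = (xc[i] - m) * is;
      sg += gc[i];
      sgx += gc[i] * xh;
    }
    dgamma[c] = sgx;
    dbeta[c] = sg;
    if (training) {
      const double mg = ga * sg / n, mgx = ga * sgx / n;
      for (R_xlen_t i = 0; i < n; ++i) {
        const double xh = (xc[i] - m) * is;
        dc[i] = is * (ga * gc[i] - mg - xh * mgx);
      }
    } else {
      for (R_xlen_t i = 0; i < n; ++i) dc[i] = is * ga * gc[i];
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

static HOT_CLONES NumericMatrix cpp_prelu_fwd_impl(const NumericMatrix& x, double alpha) {
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  NumericMatrix y(x.nrow(), x.ncol());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : alpha * xp[i];
  return y;
}

static HOT_CLONES List cpp_prelu_bwd_impl(const NumericMatrix& g, const NumericMatrix& x, double alpha) {
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  NumericMatrix dx(x.nrow(), x.ncol());
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* dp = dx.begin();
  double da = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (xp[i] > 0) {
      dp[i] = gp[i];
    } else {
      dp[i] = alpha * gp[i];
      da += gp[i] * xp[i];
    }
  }
  return List::create(_["dx"] = dx, _["dalpha"] = da);
}

// [[Rcpp::export]]
List cpp_colstats(const NumericMatrix& x) {
  return cpp_colstats_impl(x);
}

// [[Rcpp::export]]
NumericMatrix cpp_affine_cols(const NumericMatrix& x, const NumericVector& a,
                              const NumericVector& b) {
  return cpp_affine_cols_impl(x, a, b);
}

// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& g, const NumericMatrix& x,
                const NumericVector& gamma, const NumericVector& mu,
                const NumericVector& istd, bool training) {
  return cpp_bn_bwd_impl(g, x, gamma, mu, istd, training);
}

// [[Rcpp::export]]
NumericMatrix cpp_prelu_fwd(const NumericMatrix& x, double alpha) {
  return cpp_prelu_fwd_impl(x, alpha);
}

// [[Rcpp::export]]
List cpp_prelu_bwd(const NumericMatrix& g, const NumericMatrix& x, double alpha) {
  return cpp_prelu_bwd_impl(g, x, alpha);
}
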