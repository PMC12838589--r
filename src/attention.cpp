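// Fused single-head scaled-dot-product attention for the token layout
// (N*B) x C, rows grouped by sample. The softmax matrix is returned
// row-major per sample (length N*N*B) so the backward pass can reuse it
// without re-materializing large R intermediates.

#include <Rcpp.h>

#if defined(__x86_64__) && defined(__GNUC__) && !defined(__clang__)
#define HOT_CLONES __attribute__((target_clones("arch=haswell", "default")))
#else
#define HOT_CLONES
#endif


#include <vector>
#include <cmath>
using namespace Rcpp;

// copy sample b of a col-major (N*B x C) matrix into a row-major N x C buffer
static void load_rows(const double* M, R_xlen_t rows, int N, int C, int b,
                      std::vector<double>& buf) {
  for (int c = 0; c < C; ++c) {
    const double* col = M + (R_xlen_t)c * rows + (R_xlen_t)b * N;
    for (int i = 0; i < N; ++i) buf[(R_xlen_t)i * C + c] = col[i];
  }
}

static void store_rows(double* M, R_xlen_t rows, int N, int C, int b,
                       const std::vector<double>& buf) {
  for (int c = 0; c < C; ++c) {
    double* col = M + (R_xlen_t)c * rows + (R_xlen_t)b * N;
    for (int i = 0; i < N; ++i) col[i] = buf[(R_xlen_t)i * C + c];
  }
}

static HOT_CLONES List cpp_attention_fwd_impl(const NumericMatrix& Q, const NumericMatrix& K,
                       const NumericMatrix& V, int B, double scale) {
  const int C = Q.ncol();
  const int N = Q.nrow() / B;
  const R_xlen_t rows = Q.nrow();
  NumericMatrix out(rows, C);
  NumericVector Pstore((R_xlen_t)N * N * B);
  std::vector<double> q((R_xlen_t)N * C), k((R_xlen_t)N * C), v((R_xlen_t)N * C),
      o((R_xlen_t)N * C);
  const double inv = 1.0 / scale;
  for (int b = 0; b < B; ++b) {
    load_rows(Q.begin(), rows, N, C, b, q);
    load_rows(K.begin(), rows, N, C, b, k);
    load_rows(V.begin(), rows, N, C, b, v);
    double* Pb = Pstore.begin() + (R_xlen_t)b * N * N;
    for (int i = 0; i < N; ++i) {
      double* srow = Pb + (R_xlen_t)i * N;
      const double* qi = &q[(R_xlen_t)i * C];
      double mx = -1e300;
      for (int j = 0; j < N; ++j) {
        const double* kj = &k[(R_xlen_t)j * C];
        double s = 0.0;
        for (int c = 0; c < C; ++c) s += qi[c] * kj[c];
        s *= inv;
        srow[j] = s;
        if (s > mx) mx = s;
      }
      double z = 0.0;
      for (int j = 0; j < N; ++j) { srow[j] = std::exp(srow[j] - mx); z += srow[j]; }
      const double izn = 1.0 / z;
      double* orow = &o[(R_xlen_t)i * C];
      for (int c = 0; c < C; ++c) orow[c] = 0.0;
      for (int j = 0; j < N; ++j) {
        const double p = srow[j] * izn;
        srow[j] = p;
        const double* vj = &v[(R_xlen_t)j * C];
        for (int c = 0; c < C; ++c) orow[c] += p * vj[c];
      }
    }
    store_rows(out.begin(), rows, N, C, b, o);
  }
  return List::create(_["out"] = out, _["P"] = Pstore);
}

static HOT_CLONES List cpp_attention_bwd_impl(const NumericVector& Pstore, const NumericMatrix& Q,
                       const NumericMatrix& K, const NumericMatrix& V,
                       const NumericMatrix& gOut, int B, double scale) {
  const int C = Q.ncol();
  const int N = Q.nrow() / B;
  const R_xlen_t rows = Q.nrow();
  NumericMatrix dQ(rows, C), dK(rows, C), dV(rows, C);
  std::vector<double> q((R_xlen_t)N * C), k((R_xlen_t)N * C), v((R_xlen_t)N * C),
      go((R_xlen_t)N * C), dq((R_xlen_t)N * C), dk((R_xlen_t)N * C),
      dv((R_xlen_t)N * C), dsrow(N);
  const double inv = 1.0 / scale;
  for (int b = 0; b < B; ++b) {
    load_rows(Q.begin(), rows, N, C, b, q);
    load_rows(K.begin(), rows, N, C, b, k);
    load_rows(V.begin(), rows, N, C, b, v);
    load_rows(gOut.begin(), rows, N, C, b, go);
    std::fill(dq.begin(), dq.end(), 0.0);
    std::fill(dk.begin(), dk.end(), 0.0);
    std::fill(dv.begin(), dv.end(), 0.0);
    const double* Pb = Pstore.begin() + (R_xlen_t)b * N * N;
    for (int i = 0; i < N; ++i) {
      const double* prow = Pb + (R_xlen_t)i * N;
      const double* grow = &go[(R_xlen_t)i * C];
      // dP(i,j) = <gOut_i, V_j>; dV_j += P(i,j) * gOut_i
      double dot_pd = 0.0;
      for (int j = 0; j < N; ++j) {
        const double* vj = &v[(R_xlen_t)j * C];
        double* dvj = &dv[(R_xlen_t)j * C];
        double dp = 0.0;
        const double p = prow[j];
        for (int c = 0; c < C; ++c) {
          dp += grow[c] * vj[c];
          dvj[c] += p * grow[c];
        }
        dsrow[j] = dp;
        dot_pd += p * dp;
      }
      // softmax backward and scale; accumulate dQ, dK
      const double* qi = &q[(R_xlen_t)i * C];
      double* dqi = &dq[(R_xlen_t)i * C];
      for (int j = 0; j < N; ++j) {
        const double ds = prow[j] * (dsrow[j] - dot_pd) * inv;
        if (ds == 0.0) continue;
        const double* kj = &k[(R_xlen_t)j * C];
        double* dkj = &dk[(R_xlen_t)j * C];
        for (int c = 0; c < C; ++c) {
          dqi[c] += ds * kj[c];
          dkj[c] += ds * qi[c];
        }
      }
    }
    store_rows(dQ.begin(), rows, N, C, b, dq);
    store_rows(dK.begin(), rows, N, C, b, dk);
    store_rows(dV.begin(), rows, N, C, b, dv);
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}

// [[Rcpp::export]]
List cpp_attention_fwd(const NumericMatrix& Q, const NumericMatrix& K,
                       const NumericMatrix& V, int B, double scale) {
  return cpp_attention_fwd_impl(Q, K, V, B, scale);
}

// [[Rcpp::export]]
List cpp_attention_bwd(const NumericVector& Pstore, const NumericMatrix& Q,
                       const NumericMatrix& K, const NumericMatrix& V,
                       const NumericMatrix& gOut, int B, double scale) {
  return cpp_attention_bwd_impl(Pstore, Q, K, V, gOut, B, scale);
}
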