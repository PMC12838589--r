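// Direct 3D convolution kernels (forward, input-gradient, weight-gradient)
// on the package's activation layout: (S*B) x C matrices, rows grouped by
// sample, spatial order x-fastest. Per-sample feature maps are staged in
// channel-contiguous (row-major) scratch buffers so the inner loops run
// vectorized fused multiply-adds over the channel dimension while staying
// cache-resident.
//
// Weight layout: (K * C_in) x C_out, tap index (x-fastest over the kernel
// window) fastest within each input-channel block.

#include <Rcpp.h>

#if defined(__x86_64__) && defined(__GNUC__) && !defined(__clang__)
#define HOT_CLONES __attribute__((target_clones("arch=haswell", "default")))
#else
#define HOT_CLONES
#endif


#include <vector>
using namespace Rcpp;

static inline int out_len(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

struct ConvGeom {
  int nx, ny, nz, kx, ky, kz, sx, sy, sz, px, py, pz;
  int ox, oy, oz, S, So, K;
  ConvGeom(IntegerVector grid, IntegerVector kshape, IntegerVector stride,
           IntegerVector pad) {
    nx = grid[0]; ny = grid[1]; nz = grid[2];
    kx = kshape[0]; ky = kshape[1]; kz = kshape[2];
    sx = stride[0]; sy = stride[1]; sz = stride[2];
    px = pad[0]; py = pad[1]; pz = pad[2];
    ox = out_len(nx, kx, sx, px); oy = out_len(ny, ky, sy, py);
    oz = out_len(nz, kz, sz, pz);
    S = nx * ny * nz; So = ox * oy * oz; K = kx * ky * kz;
  }
  static inline void xrange(int o, int n, int s, int p, int d, int& a, int& b) {
    int lo = p - d;
    a = lo <= 0 ? 0 : (lo + s - 1) / s;
    int hi = n - 1 + p - d;
    b = hi < 0 ? 0 : hi / s + 1;
    if (b > o) b = o;
    if (a > b) a = b;
  }
};

// col-major sample block (n rows from row b*n of an (n*B x C) matrix) to a
// row-major n x C buffer, and back
static void to_rowmajor(const double* M, R_xlen_t rows, int n, int C, int b,
                        double* buf) {
  for (int c = 0; c < C; ++c) {
    const double* col = M + (R_xlen_t)c * rows + (R_xlen_t)b * n;
    for (int i = 0; i < n; ++i) buf[(R_xlen_t)i * C + c] = col[i];
  }
}

static void from_rowmajor(double* M, R_xlen_t rows, int n, int C, int b,
                          const double* buf) {
  for (int c = 0; c < C; ++c) {
    double* col = M + (R_xlen_t)c * rows + (R_xlen_t)b * n;
    for (int i = 0; i < n; ++i) col[i] = buf[(R_xlen_t)i * C + c];
  }
}

static HOT_CLONES NumericMatrix cpp_conv3d_fwd_impl(const NumericMatrix& x, const NumericMatrix& W,
                             IntegerVector grid, IntegerVector kshape,
                             IntegerVector stride, IntegerVector pad, int B) {
  ConvGeom g(grid, kshape, stride, pad);
  const int Cin = x.ncol(), Cout = W.ncol();
  NumericMatrix Y(g.So * B, Cout);
  const double* wp = W.begin();
  const R_xlen_t wrows = W.nrow();
  std::vector<double> yt((R_xlen_t)g.So * Cout), wbuf(Cout);
  for (int b = 0; b < B; ++b) {
    std::fill(yt.begin(), yt.end(), 0.0);
    for (int dz = 0; dz < g.kz; ++dz)
      for (int dy = 0; dy < g.ky; ++dy)
        for (int dx = 0; dx < g.kx; ++dx) {
          const int k = dx + dy * g.kx + dz * g.kx * g.ky;
          int xa, xb;
          ConvGeom::xrange(g.ox, g.nx, g.sx, g.px, dx, xa, xb);
          for (int cin = 0; cin < Cin; ++cin) {
            const double* xc = x.begin() + (R_xlen_t)cin * x.nrow() +
                               (R_xlen_t)b * g.S;
            const double* wrow = wp + (R_xlen_t)(k + cin * g.K);
            for (int c = 0; c < Cout; ++c) wbuf[c] = wrow[(R_xlen_t)c * wrows];
            const double* __restrict__ wb = wbuf.data();
            for (int z = 0; z < g.oz; ++z) {
              const int iz = z * g.sz - g.pz + dz;
              if (iz < 0 || iz >= g.nz) continue;
              for (int y = 0; y < g.oy; ++y) {
                const int iy = y * g.sy - g.py + dy;
                if (iy < 0 || iy >= g.ny) continue;
                const double* xr = xc + iy * g.nx + iz * g.nx * g.ny - g.px + dx;
                double* __restrict__ yrow =
                    yt.data() + ((R_xlen_t)(y * g.ox + z * g.ox * g.oy)) * Cout;
                for (int xo = xa; xo < xb; ++xo) {
                  const double xv = xr[xo * g.sx];
                  double* __restrict__ yo = yrow + (R_xlen_t)xo * Cout;
                  for (int c = 0; c < Cout; ++c) yo[c] += wb[c] * xv;
                }
              }
            }
          }
        }
    from_rowmajor(Y.begin(), Y.nrow(), g.So, Cout, b, yt.data());
  }
  return Y;
}

static HOT_CLONES NumericMatrix cpp_conv3d_bwd_x_impl(const NumericMatrix& gY, const NumericMatrix& W,
                               IntegerVector grid, IntegerVector kshape,
                               IntegerVector stride, IntegerVector pad, int B) {
  ConvGeom g(grid, kshape, stride, pad);
  const int Cout = W.ncol();
  const int Cin = W.nrow() / g.K;
  NumericMatrix dX(g.S * B, Cin);
  const double* wp = W.begin();
  const R_xlen_t wrows = W.nrow();
  std::vector<double> dxt((R_xlen_t)g.S * Cin), wbuf(Cin);
  for (int b = 0; b < B; ++b) {
    std::fill(dxt.begin(), dxt.end(), 0.0);
    for (int dz = 0; dz < g.kz; ++dz)
      for (int dy = 0; dy < g.ky; ++dy)
        for (int dx = 0; dx < g.kx; ++dx) {
          const int k = dx + dy * g.kx + dz * g.kx * g.ky;
          int xa, xb;
          ConvGeom::xrange(g.ox, g.nx, g.sx, g.px, dx, xa, xb);
          for (int cout = 0; cout < Cout; ++cout) {
            const double* gc = gY.begin() + (R_xlen_t)cout * gY.nrow() +
                               (R_xlen_t)b * g.So;
            for (int c = 0; c < Cin; ++c)
              wbuf[c] = wp[(R_xlen_t)cout * wrows + (k + c * g.K)];
            const double* __restrict__ wb = wbuf.data();
            for (int z = 0; z < g.oz; ++z) {
              const int iz = z * g.sz - g.pz + dz;
              if (iz < 0 || iz >= g.nz) continue;
              for (int y = 0; y < g.oy; ++y) {
                const int iy = y * g.sy - g.py + dy;
                if (iy < 0 || iy >= g.ny) continue;
                const double* grow = gc + y * g.ox + z * g.ox * g.oy;
                double* dxbase =
                    dxt.data() + ((R_xlen_t)(iy * g.nx + iz * g.nx * g.ny - g.px + dx)) * Cin;
                for (int xo = xa; xo < xb; ++xo) {
                  const double gv = grow[xo];
                  double* __restrict__ dr = dxbase + (R_xlen_t)(xo * g.sx) * Cin;
                  for (int c = 0; c < Cin; ++c) dr[c] += wb[c] * gv;
                }
              }
            }
          }
        }
    from_rowmajor(dX.begin(), dX.nrow(), g.S, Cin, b, dxt.data());
  }
  return dX;
}

static HOT_CLONES NumericMatrix cpp_conv3d_bwd_w_impl(const NumericMatrix& x, const NumericMatrix& gY,
                               IntegerVector grid, IntegerVector kshape,
                               IntegerVector stride, IntegerVector pad, int B) {
  ConvGeom g(grid, kshape, stride, pad);
  const int Cin = x.ncol(), Cout = gY.ncol();
  NumericMatrix dW(g.K * Cin, Cout);
  std::vector<double> xt((R_xlen_t)g.S * Cin), gt((R_xlen_t)g.So * Cout),
      acc((R_xlen_t)Cin * Cout);
  for (int b = 0; b < B; ++b) {
    to_rowmajor(x.begin(), x.nrow(), g.S, Cin, b, xt.data());
    to_rowmajor(gY.begin(), gY.nrow(), g.So, Cout, b, gt.data());
    for (int dz = 0; dz < g.kz; ++dz)
      for (int dy = 0; dy < g.ky; ++dy)
        for (int dx = 0; dx < g.kx; ++dx) {
          const int k = dx + dy * g.kx + dz * g.kx * g.ky;
          int xa, xb;
          ConvGeom::xrange(g.ox, g.nx, g.sx, g.px, dx, xa, xb);
          std::fill(acc.begin(), acc.end(), 0.0);
          for (int z = 0; z < g.oz; ++z) {
            const int iz = z * g.sz - g.pz + dz;
            if (iz < 0 || iz >= g.nz) continue;
            for (int y = 0; y < g.oy; ++y) {
              const int iy = y * g.sy - g.py + dy;
              if (iy < 0 || iy >= g.ny) continue;
              const double* gbase = gt.data() + ((R_xlen_t)(y * g.ox + z * g.ox * g.oy)) * Cout;
              const double* xbase =
                  xt.data() + ((R_xlen_t)(iy * g.nx + iz * g.nx * g.ny - g.px + dx)) * Cin;
              for (int xo = xa; xo < xb; ++xo) {
                const double* __restrict__ grow = gbase + (R_xlen_t)xo * Cout;
                const double* __restrict__ xrow = xbase + (R_xlen_t)(xo * g.sx) * Cin;
                double* __restrict__ a = acc.data();
                for (int ci = 0; ci < Cin; ++ci) {
                  const double xv = xrow[ci];
                  double* arow = a + (R_xlen_t)ci * Cout;
                  for (int co = 0; co < Cout; ++co) arow[co] += xv * grow[co];
                }
              }
            }
          }
          // fold the tap's accumulator into dW
          for (int ci = 0; ci < Cin; ++ci)
            for (int co = 0; co < Cout; ++co)
              dW(k + ci * g.K, co) += acc[(R_xlen_t)ci * Cout + co];
        }
  }
  return dW;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3d_fwd(const NumericMatrix& x, const NumericMatrix& W,
                             IntegerVector grid, IntegerVector kshape,
                             IntegerVector stride, IntegerVector pad, int B) {
  return cpp_conv3d_fwd_impl(x, W, grid, kshape, stride, pad, B);
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3d_bwd_x(const NumericMatrix& gY, const NumericMatrix& W,
                               IntegerVector grid, IntegerVector kshape,
                               IntegerVector stride, IntegerVector pad, int B) {
  return cpp_conv3d_bwd_x_impl(gY, W, grid, kshape, stride, pad, B);
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3d_bwd_w(const NumericMatrix& x, const NumericMatrix& gY,
                               IntegerVector grid, IntegerVector kshape,
                               IntegerVector stride, IntegerVector pad, int B) {
  return cpp_conv3d_bwd_w_impl(x, gY, grid, kshape, stride, pad, B);
}
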