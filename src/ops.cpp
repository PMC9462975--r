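#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>
#include <cmath>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Feature maps are C x N matrices over voxels of an H x W x S grid,
// voxel n = x + H*y + H*W*z (0-based, x fastest: R array order).

// Lowered convolution: column n of the result stacks, offset block by offset
// block, the C input channels at voxel n shifted by that kernel offset
// (zero-padded at the grid border). Channel blocks are contiguous in both the
// source and the destination, so the kernel is a sweep of C-double memcpys.
// [[Rcpp::export]]
NumericMatrix cpp_im2col3(const NumericMatrix& x, int H, int W, int S,
                          int k, int pad) {
  const int C = x.nrow(), K3 = k * k * k;
  const R_xlen_t N = (R_xlen_t)H * W * S;
  NumericMatrix col(K3 * C, N);
  const double* px = REAL(x);
  double* pc = REAL(col);
  const R_xlen_t ld = col.nrow();
  const size_t blk = (size_t)C * sizeof(double);
  for (int o = 0; o < K3; ++o) {
    const int dx = o % k - pad, dy = (o / k) % k - pad, dz = o / (k * k) - pad;
    const int x0 = std::max(0, -dx), x1 = std::min(H, H - dx);
    const int y0 = std::max(0, -dy), y1 = std::min(W, W - dy);
    const int z0 = std::max(0, -dz), z1 = std::min(S, S - dz);
    for (int z = z0; z < z1; ++z)
      for (int y = y0; y < y1; ++y) {
        const R_xlen_t n0 = x0 + (R_xlen_t)H * (y + (R_xlen_t)W * z);
        const R_xlen_t m0 = (x0 + dx) +
          (R_xlen_t)H * ((y + dy) + (R_xlen_t)W * (z + dz));
        const double* src = px + m0 * C;
        double* dst = pc + n0 * ld + (R_xlen_t)o * C;
        for (int xx = x0; xx < x1; ++xx) {
          std::memcpy(dst, src, blk);
          src += C; dst += ld;
        }
      }
  }
  return col;
}

// adjoint of cpp_im2col3: scatter-adds the lowered gradient back to voxels
// [[Rcpp::export]]
NumericMatrix cpp_col2im3(const NumericMatrix& dcol, int C, int H, int W,
                          int S, int k, int pad) {
  const int K3 = k * k * k;
  const R_xlen_t N = (R_xlen_t)H * W * S;
  NumericMatrix dx_(C, N);
  const double* pc = REAL(dcol);
  double* pd = REAL(dx_);
  const R_xlen_t ld = dcol.nrow();
  for (int o = 0; o < K3; ++o) {
    const int dx = o % k - pad, dy = (o / k) % k - pad, dz = o / (k * k) - pad;
    const int x0 = std::max(0, -dx), x1 = std::min(H, H - dx);
    const int y0 = std::max(0, -dy), y1 = std::min(W, W - dy);
    const int z0 = std::max(0, -dz), z1 = std::min(S, S - dz);
    for (int z = z0; z < z1; ++z)
      for (int y = y0; y < y1; ++y) {
        const R_xlen_t n0 = x0 + (R_xlen_t)H * (y + (R_xlen_t)W * z);
        const R_xlen_t m0 = (x0 + dx) +
          (R_xlen_t)H * ((y + dy) + (R_xlen_t)W * (z + dz));
        const double* src = pc + n0 * ld + (R_xlen_t)o * C;
        double* dst = pd + m0 * C;
        for (int xx = x0; xx < x1; ++xx) {
          for (int c = 0; c < C; ++c) dst[c] += src[c];
          src += ld; dst += C;
        }
      }
  }
  return dx_;
}

// ---- direct BLAS 3x3x3 convolution (padded-buffer offset GEMMs) -----------
// The hot path used by the network. The input is copied once into a buffer
// with a one-voxel zero halo; each of the 27 kernel offsets is then a single
// dgemm over a contiguous column range of that buffer (a shifted view is just
// a pointer offset in the padded raster). Matches the im2col route exactly;
// the im2col functions above stay as the slow independent reference.

static void pad_copy_in(const double* x, double* xp, int C, int H, int W,
                        int S) {
  const int Hp = H + 2, Wp = W + 2;
  const size_t run = (size_t)C * H * sizeof(double);
  for (int z = 0; z < S; ++z)
    for (int y = 0; y < W; ++y) {
      const double* src = x + (size_t)C * ((size_t)H * (y + (size_t)W * z));
      double* dst = xp + (size_t)C *
        (1 + (size_t)Hp * ((y + 1) + (size_t)Wp * (z + 1)));
      std::memcpy(dst, src, run);
    }
}

static void pad_copy_out(const double* yp, double* y, int C, int H, int W,
                         int S) {
  const int Hp = H + 2, Wp = W + 2;
  const size_t run = (size_t)C * H * sizeof(double);
  for (int z = 0; z < S; ++z)
    for (int y_ = 0; y_ < W; ++y_) {
      const double* src = yp + (size_t)C *
        (1 + (size_t)Hp * ((y_ + 1) + (size_t)Wp * (z + 1)));
      double* dst = y + (size_t)C * ((size_t)H * (y_ + (size_t)W * z));
      std::memcpy(dst, src, run);
    }
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3_fwd(const NumericMatrix& x, const NumericMatrix& W_,
                            const NumericVector& b, int H, int W, int S) {
  const int Cin = x.nrow(), Cout = W_.nrow();
  const int Hp = H + 2, Wp = W + 2, Sp = S + 2;
  const R_xlen_t N = (R_xlen_t)H * W * S, Np = (R_xlen_t)Hp * Wp * Sp;
  std::vector<double> xp((size_t)Cin * Np, 0.0), ypad((size_t)Cout * Np, 0.0);
  pad_copy_in(REAL(x), xp.data(), Cin, H, W, S);
  const double one = 1.0;
  for (int o = 0; o < 27; ++o) {
    const int dx = o % 3 - 1, dy = (o / 3) % 3 - 1, dz = o / 9 - 1;
    const R_xlen_t delta = dx + (R_xlen_t)Hp * (dy + (R_xlen_t)Wp * dz);
    const R_xlen_t a = std::max((R_xlen_t)0, -delta);
    const R_xlen_t ncols = Np - std::llabs((long long)delta);
    const int m = Cout, k = Cin, n = (int)ncols;
    F77_CALL(dgemm)("N", "N", &m, &n, &k, &one,
                    REAL(W_) + (size_t)o * Cin * Cout, &m,
                    xp.data() + (size_t)(a + delta) * Cin, &k, &one,
                    ypad.data() + (size_t)a * Cout, &m FCONE FCONE);
  }
  NumericMatrix out(Cout, N);
  pad_copy_out(ypad.data(), REAL(out), Cout, H, W, S);
  double* po = REAL(out);
  for (R_xlen_t j = 0; j < N; ++j)
    for (int c = 0; c < Cout; ++c) po[j * Cout + c] += b[c];
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(const NumericMatrix& x, const NumericMatrix& W_,
                   const NumericMatrix& dy, int H, int W, int S) {
  const int Cin = x.nrow(), Cout = W_.nrow();
  const int Hp = H + 2, Wp = W + 2, Sp = S + 2;
  const R_xlen_t N = (R_xlen_t)H * W * S, Np = (R_xlen_t)Hp * Wp * Sp;
  std::vector<double> xp((size_t)Cin * Np, 0.0), dyp((size_t)Cout * Np, 0.0),
    dxp((size_t)Cin * Np, 0.0);
  pad_copy_in(REAL(x), xp.data(), Cin, H, W, S);
  pad_copy_in(REAL(dy), dyp.data(), Cout, H, W, S);
  NumericMatrix dW(Cout, 27 * Cin);
  const double one = 1.0, zero = 0.0;
  for (int o = 0; o < 27; ++o) {
    const int dx = o % 3 - 1, dy_ = (o / 3) % 3 - 1, dz = o / 9 - 1;
    const R_xlen_t delta = dx + (R_xlen_t)Hp * (dy_ + (R_xlen_t)Wp * dz);
    const R_xlen_t a = std::max((R_xlen_t)0, -delta);
    const int ncols = (int)(Np - std::llabs((long long)delta));
    const int m = Cout, k = Cin;
    // dW_o = dY_pad[, a..) %*% t(X_pad[, a+delta..))
    F77_CALL(dgemm)("N", "T", &m, &k, &ncols, &one,
                    dyp.data() + (size_t)a * Cout, &m,
                    xp.data() + (size_t)(a + delta) * Cin, &k, &zero,
                    REAL(dW) + (size_t)o * Cin * Cout, &m FCONE FCONE);
    // dX_pad[, a+delta..) += t(W_o) %*% dY_pad[, a..)
    F77_CALL(dgemm)("T", "N", &k, &ncols, &m, &one,
                    REAL(W_) + (size_t)o * Cin * Cout, &m,
                    dyp.data() + (size_t)a * Cout, &m, &one,
                    dxp.data() + (size_t)(a + delta) * Cin, &k FCONE FCONE);
  }
  NumericMatrix dx_(Cin, N);
  pad_copy_out(dxp.data(), REAL(dx_), Cin, H, W, S);
  NumericVector db(Cout);
  const double* pdy = REAL(dy);
  for (R_xlen_t j = 0; j < N; ++j)
    for (int c = 0; c < Cout; ++c) db[c] += pdy[j * Cout + c];
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx_);
}

// 2x2x2 max pooling, stride 2. Returns pooled C x N/8 matrix and the
// 1-based input column index of each maximum (per channel) for backprop.
// [[Rcpp::export]]
List cpp_maxpool3_fwd(const NumericMatrix& x, int H, int W, int S) {
  const int C = x.nrow();
  const int Ho = H / 2, Wo = W / 2, So = S / 2, No = Ho * Wo * So;
  NumericMatrix out(C, No);
  IntegerMatrix arg(C, No);
  for (int z = 0; z < So; ++z)
    for (int y = 0; y < Wo; ++y)
      for (int xx = 0; xx < Ho; ++xx) {
        const int n = xx + Ho * (y + Wo * z);
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; int bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int m = (2 * xx + dx) + H * ((2 * y + dy) + W * (2 * z + dz));
                const double v = x(c, m);
                if (v > best) { best = v; bi = m; }
              }
          out(c, n) = best;
          arg(c, n) = bi + 1;
        }
      }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool3_bwd(const NumericMatrix& dy, const IntegerMatrix& arg,
                               int Nin) {
  const int C = dy.nrow(), No = dy.ncol();
  NumericMatrix dx_(C, Nin);
  for (int n = 0; n < No; ++n)
    for (int c = 0; c < C; ++c)
      dx_(c, arg(c, n) - 1) += dy(c, n);
  return dx_;
}

// Row-wise max with 1-based argmax (global spatial max pooling per channel).
// [[Rcpp::export]]
List cpp_row_max(const NumericMatrix& x) {
  const int C = x.nrow(), N = x.ncol();
  NumericVector v(C);
  IntegerVector idx(C);
  for (int c = 0; c < C; ++c) {
    double best = x(c, 0); int bi = 0;
    for (int n = 1; n < N; ++n)
      if (x(c, n) > best) { best = x(c, n); bi = n; }
    v[c] = best; idx[c] = bi + 1;
  }
  return List::create(_["max"] = v, _["which"] = idx);
}

// For every point of A (n x 3, voxel coords), the minimum spacing-scaled
// Euclidean distance to any point of B (m x 3).
// [[Rcpp::export]]
NumericVector cpp_min_dists(const NumericMatrix& A, const NumericMatrix& B,
                            const NumericVector& spacing) {
  const int n = A.nrow(), m = B.nrow();
  const double s0 = spacing[0], s1 = spacing[1], s2 = spacing[2];
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double a0 = A(i, 0) * s0, a1 = A(i, 1) * s1, a2 = A(i, 2) * s2;
    for (int j = 0; j < m; ++j) {
      const double d0 = a0 - B(j, 0) * s0;
      const double d1 = a1 - B(j, 1) * s1;
      const double d2 = a2 - B(j, 2) * s2;
      const double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

static inline double crf_kernel(double d2, double di, double w1, double w2,
                                double inv2sa2, double inv2sb2, double inv2sg2) {
  return w1 * std::exp(-d2 * inv2sa2 - di * di * inv2sb2) +
         w2 * std::exp(-d2 * inv2sg2);
}

// Mean-field iterations for the fully-connected Potts CRF.
// unary: C x N matrix of psi_u; intensity: length-N vector (normalized);
// radius <= 0 runs the exact dense O(N^2) message pass, otherwise messages
// are truncated to the cubic neighborhood |dx|,|dy|,|dz| <= radius.
// Returns the per-voxel marginals Q (C x N) after `iters` rounds.
// [[Rcpp::export]]
NumericMatrix cpp_crf_meanfield(const NumericMatrix& unary,
                                const NumericVector& intensity,
                                int H, int W, int S,
                                double w1, double w2,
                                double sa, double sb, double sg,
                                int iters, int radius) {
  const int C = unary.nrow(), N = H * W * S;
  const double inv2sa2 = 1.0 / (2.0 * sa * sa);
  const double inv2sb2 = 1.0 / (2.0 * sb * sb);
  const double inv2sg2 = 1.0 / (2.0 * sg * sg);
  NumericMatrix Q(C, N);
  // Q^0 = softmax(-psi_u), i.e. the network's probabilities
  for (int n = 0; n < N; ++n) {
    double mx = R_NegInf;
    for (int c = 0; c < C; ++c) mx = std::max(mx, -unary(c, n));
    double s = 0.0;
    for (int c = 0; c < C; ++c) { Q(c, n) = std::exp(-unary(c, n) - mx); s += Q(c, n); }
    for (int c = 0; c < C; ++c) Q(c, n) /= s;
  }
  if (iters <= 0 || (w1 == 0.0 && w2 == 0.0)) {
    if (iters <= 0) return Q;
  }
  NumericMatrix Sm(C, N);   // S_i(l) = sum_j k(i,j) Q_j(l)
  NumericVector Ksum(N);    // K_i   = sum_j k(i,j)
  for (int it = 0; it < iters; ++it) {
    std::fill(Sm.begin(), Sm.end(), 0.0);
    std::fill(Ksum.begin(), Ksum.end(), 0.0);
    if (radius <= 0) {
      for (int i = 0; i < N; ++i) {
        const int xi = i % H, yi = (i / H) % W, zi = i / (H * W);
        for (int j = i + 1; j < N; ++j) {
          const int xj = j % H, yj = (j / H) % W, zj = j / (H * W);
          const double dx = xi - xj, dy = yi - yj, dz = zi - zj;
          const double d2 = dx * dx + dy * dy + dz * dz;
          const double kij = crf_kernel(d2, intensity[i] - intensity[j],
                                        w1, w2, inv2sa2, inv2sb2, inv2sg2);
          Ksum[i] += kij; Ksum[j] += kij;
          for (int c = 0; c < C; ++c) {
            Sm(c, i) += kij * Q(c, j);
            Sm(c, j) += kij * Q(c, i);
          }
        }
      }
    } else {
      for (int z = 0; z < S; ++z)
        for (int y = 0; y < W; ++y)
          for (int xx = 0; xx < H; ++xx) {
            const int i = xx + H * (y + W * z);
            for (int dz = -radius; dz <= radius; ++dz) {
              const int zj = z + dz; if (zj < 0 || zj >= S) continue;
              for (int dy = -radius; dy <= radius; ++dy) {
                const int yj = y + dy; if (yj < 0 || yj >= W) continue;
                for (int dx = -radius; dx <= radius; ++dx) {
                  if (dx == 0 && dy == 0 && dz == 0) continue;
                  const int xj = xx + dx; if (xj < 0 || xj >= H) continue;
                  const int j = xj + H * (yj + W * zj);
                  const double d2 = (double)(dx * dx + dy * dy + dz * dz);
                  const double kij = crf_kernel(d2, intensity[i] - intensity[j],
                                                w1, w2, inv2sa2, inv2sb2, inv2sg2);
                  Ksum[i] += kij;
                  for (int c = 0; c < C; ++c) Sm(c, i) += kij * Q(c, j);
                }
              }
            }
          }
    }
    // message under Potts mu: m_i(l) = sum_j k(i,j) (1 - Q_j(l)) = K_i - S_i(l)
    for (int n = 0; n < N; ++n) {
      double mx = R_NegInf;
      for (int c = 0; c < C; ++c) {
        const double lg = -unary(c, n) - (Ksum[n] - Sm(c, n));
        Q(c, n) = lg;
        mx = std::max(mx, lg);
      }
      double s = 0.0;
      for (int c = 0; c < C; ++c) { Q(c, n) = std::exp(Q(c, n) - mx); s += Q(c, n); }
      for (int c = 0; c < C; ++c) Q(c, n) /= s;
    }
  }
  return Q;
}
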