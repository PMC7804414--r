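// Compiled kernels for the CNN layers.
//
// 3x3 same-padding convolution over (H, W, N, C) column-major activations is
// computed without an explicit im2col matrix: the input is copied once into
// a zero-padded (H+2, W+2, N, C) buffer, and each of the nine kernel offsets
// becomes a single accumulating BLAS dgemm on a row-shifted view of that
// buffer (the one-pixel padding absorbs every wrap across image columns and
// batch slabs, so shifted reads never leak between images). Weights are
// (9*Cin x Cout) matrices; row block k holds offset k with offsets ordered
// dx = -1,0,1 outer, dy = -1,0,1 inner, input channels fastest.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

using namespace Rcpp;

static const int OFFS[9][2] = {
  {-1, -1}, {-1, 0}, {-1, 1}, {0, -1}, {0, 0}, {0, 1}, {1, -1}, {1, 0}, {1, 1}
}; // (dx, dy) pairs, dx outer

// Copy (H, W, N, C) into a zero-padded (H+2, W+2, N, C) buffer.
static void pad_in(const double* x, double* p, int H, int W, int N, int C) {
  const int Hp = H + 2, Wp = W + 2;
  const R_xlen_t slab = (R_xlen_t)Hp * Wp;
  std::memset(p, 0, sizeof(double) * slab * N * C);
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < W; ++w)
        std::memcpy(p + slab * (n + (R_xlen_t)N * c) + (R_xlen_t)Hp * (w + 1) + 1,
                    x + (R_xlen_t)H * W * (n + (R_xlen_t)N * c) + (R_xlen_t)H * w,
                    sizeof(double) * H);
}

// Extract the interior of a padded (H+2, W+2, N, C) buffer, adding an
// optional per-channel bias.
static void unpad_out(const double* p, double* y, int H, int W, int N, int C,
                      const double* bias) {
  const int Hp = H + 2, Wp = W + 2;
  const R_xlen_t slab = (R_xlen_t)Hp * Wp;
  for (int c = 0; c < C; ++c) {
    const double b = bias ? bias[c] : 0.0;
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < W; ++w) {
        const double* s = p + slab * (n + (R_xlen_t)N * c) + (R_xlen_t)Hp * (w + 1) + 1;
        double* d = y + (R_xlen_t)H * W * (n + (R_xlen_t)N * c) + (R_xlen_t)H * w;
        if (bias) for (int h = 0; h < H; ++h) d[h] = s[h] + b;
        else std::memcpy(d, s, sizeof(double) * H);
      }
  }
}

// [[Rcpp::export(name = ".conv3x3_fwd_cpp")]]
NumericVector conv3x3_fwd_cpp(NumericVector X, IntegerVector dims,
                              NumericMatrix W, NumericVector b) {
  const int H = dims[0], Wd = dims[1], N = dims[2], C = dims[3];
  const int Cout = W.ncol();
  const int Hp = H + 2, Wp = Wd + 2;
  const int R = Hp * Wp * N; // padded rows per channel
  std::vector<double> P((R_xlen_t)R * C), Yp((R_xlen_t)R * Cout, 0.0);
  pad_in(REAL(X), P.data(), H, Wd, N, C);
  const double one = 1.0;
  const int ldw = 9 * C;
  for (int k = 0; k < 9; ++k) {
    const int s = OFFS[k][1] + Hp * OFFS[k][0]; // row shift of the source
    const int r0 = s > 0 ? 0 : -s;              // first output row
    const int m = R - (s > 0 ? s : -s);
    F77_CALL(dgemm)("N", "N", &m, &Cout, const_cast<int*>(&C), &one,
                    P.data() + r0 + s, const_cast<int*>(&R),
                    &W[0] + (R_xlen_t)k * C, const_cast<int*>(&ldw), &one,
                    Yp.data() + r0, const_cast<int*>(&R)
                    FCONE FCONE);
  }
  NumericVector out((R_xlen_t)H * Wd * N * Cout);
  unpad_out(Yp.data(), REAL(out), H, Wd, N, Cout, REAL(b));
  out.attr("dim") = IntegerVector::create(H, Wd, N, Cout);
  return out;
}

// [[Rcpp::export(name = ".conv3x3_bwd_cpp")]]
List conv3x3_bwd_cpp(NumericVector dY, NumericVector X, IntegerVector dims,
                     NumericMatrix W) {
  const int H = dims[0], Wd = dims[1], N = dims[2], C = dims[3];
  const int Cout = W.ncol();
  const int Hp = H + 2, Wp = Wd + 2;
  const int R = Hp * Wp * N;
  std::vector<double> P((R_xlen_t)R * C), dYp((R_xlen_t)R * Cout),
      dXp((R_xlen_t)R * C, 0.0);
  pad_in(REAL(X), P.data(), H, Wd, N, C);
  pad_in(REAL(dY), dYp.data(), H, Wd, N, Cout);

  NumericMatrix dW(9 * C, Cout);
  NumericVector db(Cout), dX((R_xlen_t)H * Wd * N * C);
  const double one = 1.0;
  const int ldw = 9 * C;

  // db: plain channel sums of dY
  {
    const double* dy = REAL(dY);
    const R_xlen_t per = (R_xlen_t)H * Wd * N;
    for (int c = 0; c < Cout; ++c) {
      double s = 0;
      for (R_xlen_t i = 0; i < per; ++i) s += dy[c * per + i];
      db[c] = s;
    }
  }
  for (int k = 0; k < 9; ++k) {
    const int s = OFFS[k][1] + Hp * OFFS[k][0];
    // dW_k += (P shifted by s)^T  %*%  dYp          (C x Cout)
    {
      const int r0 = s > 0 ? 0 : -s;
      const int m = R - (s > 0 ? s : -s);
      F77_CALL(dgemm)("T", "N", const_cast<int*>(&C), &Cout, &m, &one,
                      P.data() + r0 + s, const_cast<int*>(&R),
                      dYp.data() + r0, const_cast<int*>(&R), &one,
                      &dW[0] + (R_xlen_t)k * C, const_cast<int*>(&ldw)
                      FCONE FCONE);
    }
    // dXp[q] += dYp[q - s] %*% W_k^T
    {
      const int q0 = s > 0 ? s : 0;
      const int m = R - (s > 0 ? s : -s);
      F77_CALL(dgemm)("N", "T", &m, const_cast<int*>(&C), &Cout, &one,
                      dYp.data() + q0 - s, const_cast<int*>(&R),
                      &W[0] + (R_xlen_t)k * C, const_cast<int*>(&ldw), &one,
                      dXp.data() + q0, const_cast<int*>(&R)
                      FCONE FCONE);
    }
  }
  unpad_out(dXp.data(), REAL(dX), H, Wd, N, C, nullptr);
  dX.attr("dim") = dims;
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Batch-norm normalisation given per-channel statistics: returns the
// normalised activations xhat and the scaled output in one pass.
// [[Rcpp::export(name = ".bn_apply_cpp")]]
List bn_apply_cpp(NumericVector X, int n, int C, NumericVector mu,
                  NumericVector istd, NumericVector gamma,
                  NumericVector beta) {
  NumericVector xhat((R_xlen_t)n * C), y((R_xlen_t)n * C);
  const double* x = REAL(X);
  double* xh = REAL(xhat);
  double* yy = REAL(y);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = istd[c], g = gamma[c], bt = beta[c];
    const R_xlen_t off = (R_xlen_t)n * c;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double v = (x[off + i] - m) * is;
      xh[off + i] = v;
      yy[off + i] = v * g + bt;
    }
  }
  return List::create(_["xhat"] = xhat, _["Y"] = y);
}

// Batch-norm backward: one pass computing dgamma, dbeta and dX.
// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd_cpp(NumericVector dY, NumericVector xhat, int n, int C,
                NumericVector istd, NumericVector gamma) {
  NumericVector dX((R_xlen_t)n * C), dgamma(C), dbeta(C);
  const double* dy = REAL(dY);
  const double* xh = REAL(xhat);
  double* dx = REAL(dX);
  for (int c = 0; c < C; ++c) {
    const R_xlen_t off = (R_xlen_t)n * c;
    double sg = 0, sb = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      sg += dy[off + i] * xh[off + i];
      sb += dy[off + i];
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double g = gamma[c], is = istd[c];
    const double s1 = g * sb / n, s2 = g * sg / n;
    for (R_xlen_t i = 0; i < n; ++i)
      dx[off + i] = (g * dy[off + i] - s1 - xh[off + i] * s2) * is;
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Per-channel mean and population variance.
// [[Rcpp::export(name = ".bn_stats_cpp")]]
List bn_stats_cpp(NumericVector X, int n, int C) {
  NumericVector mu(C), var(C);
  const double* x = REAL(X);
  for (int c = 0; c < C; ++c) {
    const R_xlen_t off = (R_xlen_t)n * c;
    double s = 0;
    for (R_xlen_t i = 0; i < n; ++i) s += x[off + i];
    const double m = s / n;
    double v = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double d = x[off + i] - m;
      v += d * d;
    }
    mu[c] = m;
    var[c] = v / n;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// 2x2 max pooling with argmax quadrant (0..3) for backward routing.
// [[Rcpp::export(name = ".maxpool_fwd_cpp")]]
List maxpool_fwd_cpp(NumericVector X, IntegerVector dims) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector Y((R_xlen_t)Ho * Wo * N * C);
  IntegerVector arg((R_xlen_t)Ho * Wo * N * C);
  const double* x = REAL(X);
  double* y = REAL(Y);
  int* a = INTEGER(arg);
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < Wo; ++w) {
        const R_xlen_t col0 = (R_xlen_t)H * (2 * w + (R_xlen_t)W * (n + (R_xlen_t)N * c));
        const R_xlen_t col1 = col0 + H;
        for (int h = 0; h < Ho; ++h, ++o) {
          const double v0 = x[col0 + 2 * h], v1 = x[col0 + 2 * h + 1];
          const double v2 = x[col1 + 2 * h], v3 = x[col1 + 2 * h + 1];
          double best = v0;
          int ab = 0;
          if (v1 > best) { best = v1; ab = 1; }
          if (v2 > best) { best = v2; ab = 2; }
          if (v3 > best) { best = v3; ab = 3; }
          y[o] = best;
          a[o] = ab;
        }
      }
  Y.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return List::create(_["Y"] = Y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bwd_cpp")]]
NumericVector maxpool_bwd_cpp(NumericVector dY, IntegerVector arg,
                              IntegerVector dims) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dX((R_xlen_t)H * W * N * C);
  const double* dy = REAL(dY);
  const int* a = INTEGER(arg);
  double* dx = REAL(dX);
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < Wo; ++w) {
        const R_xlen_t col0 = (R_xlen_t)H * (2 * w + (R_xlen_t)W * (n + (R_xlen_t)N * c));
        for (int h = 0; h < Ho; ++h, ++o) {
          const int ab = a[o];
          dx[col0 + (ab >= 2 ? H : 0) + 2 * h + (ab & 1)] += dy[o];
        }
      }
  dX.attr("dim") = dims;
  return dX;
}
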