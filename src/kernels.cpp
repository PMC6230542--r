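// Numerical kernels: 2D convolution (im2col + GEMM), 2x max-pooling,
// 2x bilinear un-pooling with exact adjoint, and a pixel-driven parallel-beam
// projector with its matched transpose (the MLEM system model).
//
// Array layout convention (matches R): volumes/feature maps are column-major
// (H, W, C, N); sinograms are (n_angles, n_bins) matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill `cols` ((H*W*N) x (k*k*C)) from x (H,W,C,N) with zero padding.
// Column index r = di + k*dj + k*k*c matches the flattening of a (k,k,C,Cout)
// weight array, so conv reduces to cols * W. This orientation keeps every
// inner copy contiguous in both source and destination.
static void im2col_batch(const double* x, int H, int W, int C, int N, int k,
                         arma::fmat& cols) {
  const int p = k / 2;
  cols.zeros();
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      const int oj = dj - p;
      for (int di = 0; di < k; ++di) {
        const int oi = di - p;
        const int r = di + k * dj + k * k * c;
        float* col = cols.colptr(r);
        for (int n = 0; n < N; ++n) {
          const double* xc = x + ((size_t)n * C + c) * HW;
          for (int j = 0; j < W; ++j) {
            const int sj = j + oj;
            if (sj < 0 || sj >= W) continue;
            const double* src = xc + (size_t)sj * H;
            float* dst = col + (size_t)n * HW + (size_t)j * H;
            const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
            for (int i = i0; i < i1; ++i) dst[i] = (float)src[i + oi];
          }
        }
      }
    }
  }
}

// Scatter-add of dcols ((H*W*N) x (k*k*C)) back into dx (reverse of
// im2col_batch).
static void col2im_batch_add(const arma::fmat& dcols, double* dx, int H, int W,
                             int C, int N, int k) {
  const int p = k / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      const int oj = dj - p;
      for (int di = 0; di < k; ++di) {
        const int oi = di - p;
        const int r = di + k * dj + k * k * c;
        const float* col = dcols.colptr(r);
        for (int n = 0; n < N; ++n) {
          double* xc = dx + ((size_t)n * C + c) * HW;
          for (int j = 0; j < W; ++j) {
            const int sj = j + oj;
            if (sj < 0 || sj >= W) continue;
            double* dst = xc + (size_t)sj * H;
            const float* src = col + (size_t)n * HW + (size_t)j * H;
            const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
            for (int i = i0; i < i1; ++i) dst[i + oi] += src[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b) {
  IntegerVector xd = x.attr("dim");  // H W C N
  IntegerVector wd = w.attr("dim");  // k k Cin Cout
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: input has %d channels, kernel expects %d", C, wd[2]);
  const size_t HW = (size_t)H * W;
  if (Cout == 1) {
    NumericVector y((R_xlen_t)H * (R_xlen_t)W * (R_xlen_t)N);
    y.attr("dim") = IntegerVector::create(H, W, 1, N);
    const int p = k / 2;
    for (int n = 0; n < N; ++n) {
      double* yp = y.begin() + (size_t)n * HW;
      for (size_t i = 0; i < HW; ++i) yp[i] = b[0];
      for (int c = 0; c < C; ++c) {
        const double* xc = x.begin() + ((size_t)n * C + c) * HW;
        for (int dj = 0; dj < k; ++dj) {
          const int oj = dj - p;
          for (int di = 0; di < k; ++di) {
            const int oi = di - p;
            const double wv = w[di + k * dj + (size_t)k * k * c];
            if (wv == 0) continue;
            for (int j = std::max(0, -oj); j < std::min(W, W - oj); ++j) {
              const double* src = xc + (size_t)(j + oj) * H;
              double* dst = yp + (size_t)j * H;
              const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
              for (int i = i0; i < i1; ++i) dst[i] += wv * src[i + oi];
            }
          }
        }
      }
    }
    return y;
  }
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double*>(w.begin()), (size_t)k * k * C, Cout, false));
  arma::fmat cols(HW * N, (size_t)k * k * C);
  im2col_batch(x.begin(), H, W, C, N, k, cols);
  arma::fmat Y = cols * Wm;  // (HW*N) x Cout
  NumericVector y((R_xlen_t)H*(R_xlen_t)W*(R_xlen_t)Cout*(R_xlen_t)N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  for (int c = 0; c < Cout; ++c) {
    const float* src = Y.colptr(c);
    const double bc = b[c];
    for (int n = 0; n < N; ++n) {
      double* dst = y.begin() + (size_t)n * HW * Cout + (size_t)c * HW;
      const float* s = src + (size_t)n * HW;
      for (size_t i = 0; i < HW; ++i) dst[i] = (double)s[i] + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         bool need_dx = true) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const size_t HW = (size_t)H * W;
  if (Cout == 1) {
    const int p = k / 2;
    NumericVector dwR((R_xlen_t)k * k * C);
    dwR.attr("dim") = IntegerVector::create(k, k, C, 1);
    NumericVector dx((R_xlen_t)H * (R_xlen_t)W * (R_xlen_t)C * (R_xlen_t)N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
    double db0 = 0;
    for (R_xlen_t i = 0; i < dy.size(); ++i) db0 += dy[i];
    for (int n = 0; n < N; ++n) {
      const double* gp = dy.begin() + (size_t)n * HW;
      for (int c = 0; c < C; ++c) {
        const double* xc = x.begin() + ((size_t)n * C + c) * HW;
        double* dxc = dx.begin() + ((size_t)n * C + c) * HW;
        for (int dj = 0; dj < k; ++dj) {
          const int oj = dj - p;
          for (int di = 0; di < k; ++di) {
            const int oi = di - p;
            const size_t wi = di + k * dj + (size_t)k * k * c;
            const double wv = w[wi];
            double acc = 0;
            for (int j = std::max(0, -oj); j < std::min(W, W - oj); ++j) {
              const double* xs = xc + (size_t)(j + oj) * H;
              const double* gs = gp + (size_t)j * H;
              double* ds = dxc + (size_t)(j + oj) * H;
              const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
              if (need_dx) {
                for (int i = i0; i < i1; ++i) {
                  acc += gs[i] * xs[i + oi];
                  ds[i + oi] += wv * gs[i];
                }
              } else {
                for (int i = i0; i < i1; ++i) acc += gs[i] * xs[i + oi];
              }
            }
            dwR[wi] += acc;
          }
        }
      }
    }
    NumericVector dbR(1); dbR[0] = db0;
    return List::create(_["dx"] = dx, _["dw"] = dwR, _["db"] = dbR);
  }
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(
      arma::mat(const_cast<double*>(w.begin()), (size_t)k * k * C, Cout, false));

  // Re-pack dy (H,W,Cout,N) into (HW*N) x Cout.
  arma::fmat dY(HW * N, Cout);
  for (int c = 0; c < Cout; ++c) {
    float* dst = dY.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double* src = dy.begin() + (size_t)n * HW * Cout + (size_t)c * HW;
      for (size_t i = 0; i < HW; ++i) dst[(size_t)n * HW + i] = (float)src[i];
    }
  }

  arma::fmat cols(HW * N, (size_t)k * k * C);
  im2col_batch(x.begin(), H, W, C, N, k, cols);

  arma::fmat dWm = cols.t() * dY;       // (kkC) x Cout
  arma::frowvec db = arma::sum(dY, 0);  // 1 x Cout

  NumericVector dx((R_xlen_t)H*(R_xlen_t)W*(R_xlen_t)C*(R_xlen_t)N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  if (need_dx) {
    arma::fmat dcols = dY * Wm.t();     // (HW*N) x (kkC)
    col2im_batch_add(dcols, dx.begin(), H, W, C, N, k);
  }

  NumericVector dwR((R_xlen_t)k*(R_xlen_t)k*(R_xlen_t)C*(R_xlen_t)Cout);
  dwR.attr("dim") = IntegerVector::create(k, k, C, Cout);
  std::copy(dWm.begin(), dWm.end(), dwR.begin());
  NumericVector dbR(Cout);
  std::copy(db.begin(), db.end(), dbR.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwR, _["db"] = dbR);
}

// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho*(R_xlen_t)Wo*(R_xlen_t)C*(R_xlen_t)N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho*(R_xlen_t)Wo*(R_xlen_t)C*(R_xlen_t)N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);  // 1-based linear index into x
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + ((size_t)n * C + c) * HW;
      double* yp = y.begin() + ((size_t)n * C + c) * HWo;
      int* ip = idx.begin() + ((size_t)n * C + c) * HWo;
      const size_t plane_off = ((size_t)n * C + c) * HW;
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          size_t best = (size_t)(2 * jo) * H + 2 * io;
          double bv = xp[best];
          const size_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int q = 0; q < 3; ++q)
            if (xp[cand[q]] > bv) { bv = xp[cand[q]]; best = cand[q]; }
          yp[(size_t)jo * Ho + io] = bv;
          ip[(size_t)jo * Ho + io] = (int)(plane_off + best) + 1;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// 1D half-pixel bilinear weight tables for a factor-2 upsample of length L.
static void up2_weights(int L, std::vector<int>& i0, std::vector<int>& i1,
                        std::vector<double>& w0, std::vector<double>& w1) {
  const int Lo = 2 * L;
  i0.resize(Lo); i1.resize(Lo); w0.resize(Lo); w1.resize(Lo);
  for (int i = 0; i < Lo; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    int a = (int)std::floor(s);
    double f = s - a;
    int b = a + 1;
    if (a < 0) { a = 0; b = 0; f = 0.0; }
    if (b > L - 1) { b = L - 1; a = L - 1; f = 0.0; }
    i0[i] = a; i1[i] = b; w0[i] = 1.0 - f; w1[i] = f;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> ri0, ri1, ci0, ci1;
  std::vector<double> rw0, rw1, cw0, cw1;
  up2_weights(H, ri0, ri1, rw0, rw1);
  up2_weights(W, ci0, ci1, cw0, cw1);
  NumericVector y((R_xlen_t)Ho*(R_xlen_t)Wo*(R_xlen_t)C*(R_xlen_t)N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  std::vector<double> tmp((size_t)Ho * W);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* xp = x.begin() + p * HW;
    double* yp = y.begin() + p * HWo;
    for (int j = 0; j < W; ++j) {        // rows first
      const double* col = xp + (size_t)j * H;
      double* t = tmp.data() + (size_t)j * Ho;
      for (int i = 0; i < Ho; ++i)
        t[i] = rw0[i] * col[ri0[i]] + rw1[i] * col[ri1[i]];
    }
    for (int j = 0; j < Wo; ++j) {       // then columns
      const double* c0 = tmp.data() + (size_t)ci0[j] * Ho;
      const double* c1 = tmp.data() + (size_t)ci1[j] * Ho;
      double* out = yp + (size_t)j * Ho;
      for (int i = 0; i < Ho; ++i) out[i] = cw0[j] * c0[i] + cw1[j] * c1[i];
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  std::vector<int> ri0, ri1, ci0, ci1;
  std::vector<double> rw0, rw1, cw0, cw1;
  up2_weights(H, ri0, ri1, rw0, rw1);
  up2_weights(W, ci0, ci1, cw0, cw1);
  NumericVector dx((R_xlen_t)H*(R_xlen_t)W*(R_xlen_t)C*(R_xlen_t)N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  std::vector<double> tmp((size_t)Ho * W);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* gp = dy.begin() + p * HWo;
    double* xp = dx.begin() + p * HW;
    std::fill(tmp.begin(), tmp.end(), 0.0);
    for (int j = 0; j < Wo; ++j) {       // adjoint of column pass
      const double* in = gp + (size_t)j * Ho;
      double* c0 = tmp.data() + (size_t)ci0[j] * Ho;
      double* c1 = tmp.data() + (size_t)ci1[j] * Ho;
      for (int i = 0; i < Ho; ++i) {
        c0[i] += cw0[j] * in[i];
        c1[i] += cw1[j] * in[i];
      }
    }
    for (int j = 0; j < W; ++j) {        // adjoint of row pass
      const double* t = tmp.data() + (size_t)j * Ho;
      double* col = xp + (size_t)j * H;
      for (int i = 0; i < Ho; ++i) {
        col[ri0[i]] += rw0[i] * t[i];
        col[ri1[i]] += rw1[i] * t[i];
      }
    }
  }
  return dx;
}

// Pixel-driven parallel-beam forward projection of one slice.
// img: (H, W); angles in radians measured from the +x (column) axis;
// bin_width in pixel units; scale = per-pixel path length (e.g. pixel size
// in cm so that projecting a 1/cm mu map yields a dimensionless integral).
// Pixel (row i, col j) sits at x = j - (W-1)/2, y = i - (H-1)/2.
// [[Rcpp::export]]
NumericMatrix cpp_radon_forward(NumericMatrix img, NumericVector angles,
                                int n_bins, double bin_width, double scale) {
  const int H = img.nrow(), W = img.ncol(), A = angles.size();
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  const double t0 = (n_bins - 1) / 2.0;
  NumericMatrix sino(A, n_bins);
  for (int a = 0; a < A; ++a) {
    const double ca = std::cos(angles[a]) / bin_width;
    const double sa = std::sin(angles[a]) / bin_width;
    for (int j = 0; j < W; ++j) {
      const double tx = (j - cx) * ca + t0;
      const double* col = &img(0, j);
      for (int i = 0; i < H; ++i) {
        const double v = col[i];
        if (v == 0.0) continue;
        const double t = tx + (i - cy) * sa;
        const int b0 = (int)std::floor(t);
        const double w1 = t - b0;
        if (b0 >= 0 && b0 < n_bins) sino(a, b0) += v * scale * (1.0 - w1);
        if (b0 + 1 >= 0 && b0 + 1 < n_bins) sino(a, b0 + 1) += v * scale * w1;
      }
    }
  }
  return sino;
}

// Exact transpose of cpp_radon_forward.
// [[Rcpp::export]]
NumericMatrix cpp_radon_backward(NumericMatrix sino, NumericVector angles,
                                 int H, int W, double bin_width, double scale) {
  const int A = angles.size(), n_bins = sino.ncol();
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  const double t0 = (n_bins - 1) / 2.0;
  NumericMatrix img(H, W);
  for (int a = 0; a < A; ++a) {
    const double ca = std::cos(angles[a]) / bin_width;
    const double sa = std::sin(angles[a]) / bin_width;
    for (int j = 0; j < W; ++j) {
      const double tx = (j - cx) * ca + t0;
      double* col = &img(0, j);
      for (int i = 0; i < H; ++i) {
        const double t = tx + (i - cy) * sa;
        const int b0 = (int)std::floor(t);
        const double w1 = t - b0;
        double acc = 0.0;
        if (b0 >= 0 && b0 < n_bins) acc += sino(a, b0) * (1.0 - w1);
        if (b0 + 1 >= 0 && b0 + 1 < n_bins) acc += sino(a, b0 + 1) * w1;
        col[i] += acc * scale;
      }
    }
  }
  return img;
}

// Per-channel mean and (biased) variance over (H, W, N).
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector m(C), v(C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) { s1 += xp[i]; s2 += xp[i] * xp[i]; }
    }
    const double mm = s1 / (HW * N);
    m[c] = mm;
    v[c] = std::max(s2 / (HW * N) - mm * mm, 0.0);
  }
  return List::create(_["mean"] = m, _["var"] = v);
}

// y = gamma * (x - m) / sd + beta, per channel.
// [[Rcpp::export]]
NumericVector cpp_bn_forward(NumericVector x, NumericVector m,
                             NumericVector sdv, NumericVector gamma,
                             NumericVector beta) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector y((R_xlen_t)x.size());
  y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double a = gamma[c] / sdv[c];
    const double b0 = beta[c] - a * m[c];
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + ((size_t)n * C + c) * HW;
      double* yp = y.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) yp[i] = a * xp[i] + b0;
    }
  }
  return y;
}

// Training-mode backward. Recomputes xhat from the cached input; returns
// dx, dgamma, dbeta.
// [[Rcpp::export]]
List cpp_bn_backward(NumericVector x, NumericVector dy, NumericVector m,
                     NumericVector sdv, NumericVector gamma) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  const double mtot = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  NumericVector dx((R_xlen_t)x.size());
  dx.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double isd = 1.0 / sdv[c], mc = m[c];
    double sdy = 0, sdyh = 0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + ((size_t)n * C + c) * HW;
      const double* gp = dy.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        sdy += gp[i];
        sdyh += gp[i] * (xp[i] - mc) * isd;
      }
    }
    dbeta[c] = sdy; dgamma[c] = sdyh;
    const double coef = gamma[c] * isd;
    const double mdy = sdy / mtot, mdyh = sdyh / mtot;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + ((size_t)n * C + c) * HW;
      const double* gp = dy.begin() + ((size_t)n * C + c) * HW;
      double* dp = dx.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i)
        dp[i] = coef * (gp[i] - mdy - (xp[i] - mc) * isd * mdyh);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Elementwise ReLU; backward masks by the forward output.
// [[Rcpp::export]]
NumericVector cpp_relu_forward(NumericVector x) {
  NumericVector y((R_xlen_t)x.size());
  y.attr("dim") = x.attr("dim");
  const double* in = x.begin();
  double* out = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = in[i] > 0 ? in[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector dy, NumericVector y) {
  NumericVector dx((R_xlen_t)dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* g = dy.begin();
  const double* yy = y.begin();
  double* out = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) out[i] = yy[i] > 0 ? g[i] : 0;
  return dx;
}
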