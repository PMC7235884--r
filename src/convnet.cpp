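// Batched 2-D convolution, max pooling and SGD helpers for the AK-DL
// network.  Layout convention: R arrays in column-major order with
// dimensions (H, W, C, N); kernels (K, K, C_in, C_out).  Convolution is
// stride-1 with symmetric zero padding, realised as one im2col + GEMM per
// batch so the heavy lifting is a single BLAS matrix product per layer.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Fill rows [HW*n, HW*(n+1)) of M (HW*N x K*K*C) with zero-padded patches
// of image n.  Column index = kh + K*(kw + K*c); within-image row index
// h + H*w (the column-major flattening of the output plane).
static void im2col_one(const double* x, int H, int W, int C, int K, int pad,
                       arma::mat& M, size_t row0) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + HW * c;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        double* mcol = M.colptr(kh + K * (kw + K * c)) + row0;
        for (int w = 0; w < W; ++w) {
          int iw = w + kw - pad;
          double* mc = mcol + (size_t)H * w;
          if (iw < 0 || iw >= W) {
            std::fill(mc, mc + H, 0.0);
            continue;
          }
          const double* xcol = xc + (size_t)H * iw;
          int h0 = std::max(0, pad - kh);
          int h1 = std::min(H, H + pad - kh);
          for (int h = 0; h < h0; ++h) mc[h] = 0.0;
          for (int h = h0; h < h1; ++h) mc[h] = xcol[h + kh - pad];
          for (int h = h1; h < H; ++h) mc[h] = 0.0;
        }
      }
    }
  }
}

// Adjoint: scatter-add patch gradients (rows [HW*n, ...) of Mg) back onto
// the input plane of image n.
static void col2im_one(const arma::mat& Mg, int H, int W, int C, int K,
                       int pad, double* dx, size_t row0) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    double* dxc = dx + HW * c;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const double* mcol = Mg.colptr(kh + K * (kw + K * c)) + row0;
        for (int w = 0; w < W; ++w) {
          int iw = w + kw - pad;
          if (iw < 0 || iw >= W) continue;
          double* dxcol = dxc + (size_t)H * iw;
          const double* mc = mcol + (size_t)H * w;
          int h0 = std::max(0, pad - kh);
          int h1 = std::min(H, H + pad - kh);
          for (int h = h0; h < h1; ++h) dxcol[h + kh - pad] += mc[h];
        }
      }
    }
  }
}

// Forward convolution.  When keep_patches, the im2col matrix is returned
// as an external pointer so the immediately following backward pass can
// reuse it instead of rebuilding it.
// [[Rcpp::export]]
List cpp_conv2d_forward(NumericVector x, NumericVector w,
                        NumericVector b, int pad,
                        bool keep_patches = false) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = wd[0], F = wd[3];
  if (wd[2] != C) stop("channel mismatch between input and kernel");
  const size_t HW = (size_t)H * W;

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)K * K * C, F, false);
  arma::mat* M = new arma::mat(HW * N, (size_t)K * K * C);
  for (int n = 0; n < N; ++n)
    im2col_one(x.begin() + HW * C * n, H, W, C, K, pad, *M, HW * n);
  arma::mat Y = (*M) * Wm;  // (HW*N) x F

  NumericVector y(HW * F * N);
  y.attr("dim") = IntegerVector::create(H, W, F, N);
  for (int n = 0; n < N; ++n) {
    double* yp = y.begin() + HW * F * n;
    for (int f = 0; f < F; ++f) {
      const double* yc = Y.colptr(f) + HW * n;
      const double bf = b[f];
      double* yo = yp + HW * f;
      for (size_t i = 0; i < HW; ++i) yo[i] = yc[i] + bf;
    }
  }
  if (!keep_patches) {
    delete M;
    return List::create(_["y"] = y);
  }
  XPtr<arma::mat> ptr(M, true);
  return List::create(_["y"] = y, _["patches"] = ptr);
}

// Backward pass; dx is only computed when need_dx (the gradient w.r.t.
// the network input itself is never used).  `patches` may carry the
// im2col matrix saved by the forward pass.
// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int pad, bool need_dx = true,
                         SEXP patches = R_NilValue) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = wd[0], F = wd[3];
  const size_t HW = (size_t)H * W;

  arma::mat Mown;
  arma::mat* Mp;
  if (patches != R_NilValue) {
    Mp = XPtr<arma::mat>(patches).get();
  } else {
    Mown.set_size(HW * N, (size_t)K * K * C);
    for (int n = 0; n < N; ++n)
      im2col_one(x.begin() + HW * C * n, H, W, C, K, pad, Mown, HW * n);
    Mp = &Mown;
  }
  arma::mat& M = *Mp;

  // restack dy (H, W, F, N) into DY (HW*N x F)
  arma::mat DY(HW * N, F);
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f)
      std::copy(dy.begin() + HW * (f + (size_t)F * n),
                dy.begin() + HW * (f + (size_t)F * n) + HW,
                DY.colptr(f) + HW * n);

  arma::mat dWm = M.t() * DY;  // (K*K*C) x F
  NumericVector dw(dWm.begin(), dWm.end());
  dw.attr("dim") = wd;
  NumericVector db(F);
  for (int f = 0; f < F; ++f) db[f] = arma::accu(DY.col(f));

  NumericVector dx(0);
  if (need_dx) {
    arma::mat Wm(const_cast<double*>(w.begin()), (size_t)K * K * C, F,
                 false);
    arma::mat dM = DY * Wm.t();  // (HW*N) x (K*K*C)
    dx = NumericVector(HW * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
    for (int n = 0; n < N; ++n)
      col2im_one(dM, H, W, C, K, pad, dx.begin() + HW * C * n, HW * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2.  Returns pooled values and the 1-based linear
// index of each maximum (ties toward the earliest element in column-major
// order) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;

  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector amax((size_t)Ho * Wo * C * N);

  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int dw2 = 0; dw2 < 2; ++dw2) {
            for (int dh = 0; dh < 2; ++dh) {
              size_t idx = base + (size_t)(2 * ho + dh) +
                           (size_t)H * (2 * wo + dw2);
              double v = x[idx];
              if (v > best) { best = v; bidx = idx; }
            }
          }
          y[o] = best;
          amax[o] = (int)(bidx + 1);
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector amax,
                                   IntegerVector in_dim) {
  size_t len = (size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector dx(len);
  dx.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[amax[i] - 1] += dy[i];
  return dx;
}

// LeakyReLU applied in place (the caller owns z exclusively).
// [[Rcpp::export]]
NumericVector cpp_leaky_inplace(NumericVector z, double slope) {
  double* p = z.begin();
  for (R_xlen_t i = 0; i < z.size(); ++i)
    if (p[i] < 0) p[i] *= slope;
  return z;
}

// Multiply upstream gradient da (in place) by LeakyReLU'(z), where a is
// the *activated* value: sign(a) == sign(z) because slope > 0, so the
// derivative is recoverable from the activation itself.
// [[Rcpp::export]]
NumericVector cpp_leaky_grad_inplace(NumericVector da, NumericVector a,
                                     double slope) {
  double* d = da.begin();
  const double* p = a.begin();
  for (R_xlen_t i = 0; i < da.size(); ++i)
    if (p[i] < 0) d[i] *= slope;
  return da;
}

// Classical momentum update, in place:
//   v <- mom * v - lr * (g + l2 * w);  w <- w + v
// [[Rcpp::export]]
void cpp_sgd_update(NumericVector w, NumericVector v, NumericVector g,
                    double lr, double mom, double l2) {
  double* wp = w.begin();
  double* vp = v.begin();
  const double* gp = g.begin();
  for (R_xlen_t i = 0; i < w.size(); ++i) {
    vp[i] = mom * vp[i] - lr * (gp[i] + l2 * wp[i]);
    wp[i] += vp[i];
  }
}

// ---------------------------------------------------------------------------
// Single-precision training engine.  One call trains the whole network:
// the caller supplies the initial (double) weights, the per-epoch shuffle
// orders and the uniform variates driving dropout, so training remains a
// pure function of (weights, data, orders, dropout stream).  Arithmetic is
// IEEE float32 (the customary precision for convolutional network
// training); outputs are returned as doubles.

static void im2col_one_f(const float* x, int H, int W, int C, int K, int pad,
                         arma::fmat& M, size_t row0) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const float* xc = x + HW * c;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        float* mcol = M.colptr(kh + K * (kw + K * c)) + row0;
        for (int w = 0; w < W; ++w) {
          int iw = w + kw - pad;
          float* mc = mcol + (size_t)H * w;
          if (iw < 0 || iw >= W) {
            std::fill(mc, mc + H, 0.0f);
            continue;
          }
          const float* xcol = xc + (size_t)H * iw;
          int h0 = std::max(0, pad - kh);
          int h1 = std::min(H, H + pad - kh);
          for (int h = 0; h < h0; ++h) mc[h] = 0.0f;
          for (int h = h0; h < h1; ++h) mc[h] = xcol[h + kh - pad];
          for (int h = h1; h < H; ++h) mc[h] = 0.0f;
        }
      }
    }
  }
}

static void col2im_one_f(const arma::fmat& Mg, int H, int W, int C, int K,
                         int pad, float* dx, size_t row0) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    float* dxc = dx + HW * c;
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const float* mcol = Mg.colptr(kh + K * (kw + K * c)) + row0;
        for (int w = 0; w < W; ++w) {
          int iw = w + kw - pad;
          if (iw < 0 || iw >= W) continue;
          float* dxcol = dxc + (size_t)H * iw;
          const float* mc = mcol + (size_t)H * w;
          int h0 = std::max(0, pad - kh);
          int h1 = std::min(H, H + pad - kh);
          for (int h = h0; h < h1; ++h) dxcol[h + kh - pad] += mc[h];
        }
      }
    }
  }
}

static void sgd_step_f(arma::fmat& w, arma::fmat& v, const arma::fmat& g,
                       float lr, float mom, float l2) {
  float* wp = w.memptr();
  float* vp = v.memptr();
  const float* gp = g.memptr();
  const arma::uword nel = w.n_elem;
  for (arma::uword i = 0; i < nel; ++i) {
    vp[i] = mom * vp[i] - lr * (gp[i] + l2 * wp[i]);
    wp[i] += vp[i];
  }
}

static void leaky_f(arma::fmat& z, float slope) {
  float* p = z.memptr();
  for (arma::uword i = 0; i < z.n_elem; ++i)
    if (p[i] < 0) p[i] *= slope;
}

// [[Rcpp::export]]
List cpp_akdl_train(NumericVector x, IntegerVector y, List w0,
                    List conf, List tc, List orders, List dropu) {
  IntegerVector xd = x.attr("dim");
  const int S = xd[0], N = xd[3];
  const int K = as<int>(conf["kernel_size"]), pad = as<int>(conf["conv_padding"]);
  IntegerVector filt = conf["filters"];
  const int F1 = filt[0], F2 = filt[1];
  const int FC = as<int>(conf["fc_width"]), NC = as<int>(conf["n_classes"]);
  const float slope = (float)as<double>(conf["leaky_slope"]);
  const float pdrop = (float)as<double>(conf["dropout_p"]);
  const float lr = (float)as<double>(tc["initial_learn_rate"]);
  const float mom = (float)as<double>(tc["momentum"]);
  const float l2 = (float)as<double>(tc["l2_regularization"]);
  const int bs = as<int>(tc["mini_batch_size"]);
  const int epochs = as<int>(tc["epochs"]);

  const int Sp = S / 2;                      // pooled side
  const size_t HW1 = (size_t)S * S, HW2 = (size_t)Sp * Sp;
  const int flat = (int)(HW2 * F2);

  // inputs as float, one column per sample (flattened H x W x 3)
  arma::fmat X(HW1 * 3, N);
  {
    const double* xp = x.begin();
    float* fp = X.memptr();
    for (size_t i = 0; i < HW1 * 3 * (size_t)N; ++i) fp[i] = (float)xp[i];
  }

  auto asf = [](NumericVector v, size_t r, size_t c) {
    arma::fmat m(r, c);
    for (size_t i = 0; i < r * c; ++i) m.memptr()[i] = (float)v[i];
    return m;
  };
  arma::fmat W1 = asf(w0["W1"], (size_t)K * K * 3, F1);
  arma::fmat b1 = asf(w0["b1"], F1, 1);
  arma::fmat W2 = asf(w0["W2"], (size_t)K * K * F1, F2);
  arma::fmat b2 = asf(w0["b2"], F2, 1);
  arma::fmat W3 = asf(w0["W3"], FC, (size_t)flat);
  arma::fmat b3 = asf(w0["b3"], FC, 1);
  arma::fmat W4 = asf(w0["W4"], NC, FC);
  arma::fmat b4 = asf(w0["b4"], NC, 1);
  arma::fmat vW1(arma::size(W1), arma::fill::zeros), vb1(arma::size(b1), arma::fill::zeros);
  arma::fmat vW2(arma::size(W2), arma::fill::zeros), vb2(arma::size(b2), arma::fill::zeros);
  arma::fmat vW3(arma::size(W3), arma::fill::zeros), vb3(arma::size(b3), arma::fill::zeros);
  arma::fmat vW4(arma::size(W4), arma::fill::zeros), vb4(arma::size(b4), arma::fill::zeros);

  NumericVector hist_loss(epochs), hist_acc(epochs);

  const int Bmax = bs;
  arma::fmat xb(HW1 * 3, Bmax);
  arma::fmat M1, M2, P, A2, FM, DFM, DP;
  std::vector<int> amax((size_t)HW2 * F1 * Bmax);

  for (int ep = 0; ep < epochs; ++ep) {
    IntegerVector ord = orders[ep];
    NumericVector uvec = (pdrop > 0) ? (NumericVector)dropu[ep]
                                     : NumericVector(0);
    double loss_sum = 0.0; int correct = 0;
    for (int start = 0; start < N; start += bs) {
      const int B = std::min(bs, N - start);
      const size_t r1 = HW1 * B, r2 = HW2 * B;

      for (int j = 0; j < B; ++j)
        xb.col(j) = X.col(ord[start + j] - 1);

      // conv1 + leaky
      M1.set_size(r1, (size_t)K * K * 3);
      for (int n = 0; n < B; ++n)
        im2col_one_f(xb.colptr(n), S, S, 3, K, pad, M1, HW1 * n);
      arma::fmat A1 = M1 * W1;               // (HW1*B) x F1
      for (int f = 0; f < F1; ++f) A1.col(f) += b1(f);
      leaky_f(A1, slope);

      // 2x2 max pool on each (S, S) plane; P laid out (HW2) rows per
      // sample x F1 cols, matching the im2col row convention below
      P.set_size(r2, F1);
      for (int n = 0; n < B; ++n) {
        for (int f = 0; f < F1; ++f) {
          const float* ap = A1.colptr(f) + HW1 * n;
          float* pp = P.colptr(f) + HW2 * n;
          int* am = amax.data() + (HW2 * (f + (size_t)F1 * n));
          for (int wo = 0; wo < Sp; ++wo) {
            for (int ho = 0; ho < Sp; ++ho) {
              float best = -std::numeric_limits<float>::infinity();
              int bi = 0;
              for (int dw2 = 0; dw2 < 2; ++dw2)
                for (int dh = 0; dh < 2; ++dh) {
                  int idx = (2 * ho + dh) + S * (2 * wo + dw2);
                  if (ap[idx] > best) { best = ap[idx]; bi = idx; }
                }
              pp[ho + Sp * wo] = best;
              am[ho + Sp * wo] = bi;
            }
          }
        }
      }

      // conv2 + leaky: per-sample im2col over the pooled planes
      M2.set_size(r2, (size_t)K * K * F1);
      for (int n = 0; n < B; ++n) {
        // gather sample n's pooled planes contiguously
        arma::fmat pn(HW2, F1);
        for (int f = 0; f < F1; ++f)
          std::copy(P.colptr(f) + HW2 * n, P.colptr(f) + HW2 * (n + 1),
                    pn.colptr(f));
        im2col_one_f(pn.memptr(), Sp, Sp, F1, K, pad, M2, HW2 * n);
      }
      A2.set_size(r2, F2);
      A2 = M2 * W2;
      for (int f = 0; f < F2; ++f) A2.col(f) += b2(f);
      leaky_f(A2, slope);

      // flatten: FM (flat x B), sample n = concat over f of A2 rows
      FM.set_size(flat, B);
      for (int n = 0; n < B; ++n)
        for (int f = 0; f < F2; ++f)
          std::copy(A2.colptr(f) + HW2 * n, A2.colptr(f) + HW2 * (n + 1),
                    FM.colptr(n) + HW2 * f);

      arma::fmat A3 = W3 * FM;
      A3.each_col() += b3;
      leaky_f(A3, slope);
      arma::fmat A3d = A3;
      arma::fmat mask;
      if (pdrop > 0) {
        mask.set_size(FC, B);
        const double* up = uvec.begin() + (size_t)FC * start;
        const float inv = 1.0f / (1.0f - pdrop);
        for (int j = 0; j < B; ++j)
          for (int i = 0; i < FC; ++i) {
            float m = (up[(size_t)FC * j + i] >= pdrop) ? inv : 0.0f;
            mask(i, j) = m;
            A3d(i, j) *= m;
          }
      }
      arma::fmat Z4 = W4 * A3d;
      Z4.each_col() += b4;
      // softmax + loss + accuracy
      arma::fmat Pr = Z4;
      for (int j = 0; j < B; ++j) {
        float mx = Pr.col(j).max();
        Pr.col(j) = arma::exp(Pr.col(j) - mx);
        Pr.col(j) /= arma::accu(Pr.col(j));
        int yi = y[ord[start + j] - 1];
        loss_sum -= std::log(std::max((double)Pr(yi, j), 1e-12));
        if ((Pr(1, j) >= 0.5f) == (yi == 1)) ++correct;
      }

      // backward
      arma::fmat dZ4 = Pr;
      for (int j = 0; j < B; ++j)
        dZ4(y[ord[start + j] - 1], j) -= 1.0f;
      dZ4 /= (float)B;
      arma::fmat dW4 = dZ4 * A3d.t();
      arma::fmat db4 = arma::sum(dZ4, 1);
      arma::fmat dA3 = W4.t() * dZ4;
      if (pdrop > 0) dA3 %= mask;
      // LeakyReLU': recover from activation sign
      {
        float* d = dA3.memptr(); const float* a = A3.memptr();
        for (arma::uword i = 0; i < dA3.n_elem; ++i)
          if (a[i] < 0) d[i] *= slope;
      }
      arma::fmat dW3 = dA3 * FM.t();
      arma::fmat db3 = arma::sum(dA3, 1);
      DFM.set_size(flat, B);
      DFM = W3.t() * dA3;
      {
        float* d = DFM.memptr(); const float* a = FM.memptr();
        for (arma::uword i = 0; i < DFM.n_elem; ++i)
          if (a[i] < 0) d[i] *= slope;
      }
      // unflatten DFM into DY2 (HW2*B x F2)
      arma::fmat DY2(r2, F2);
      for (int n = 0; n < B; ++n)
        for (int f = 0; f < F2; ++f)
          std::copy(DFM.colptr(n) + HW2 * f, DFM.colptr(n) + HW2 * (f + 1),
                    DY2.colptr(f) + HW2 * n);
      arma::fmat dW2 = M2.t() * DY2;
      arma::fmat db2 = arma::sum(DY2, 0).t();
      arma::fmat dM2 = DY2 * W2.t();
      DP.set_size(r2, F1);
      DP.zeros();
      for (int n = 0; n < B; ++n) {
        arma::fmat dpn(HW2, F1, arma::fill::zeros);
        col2im_one_f(dM2, Sp, Sp, F1, K, pad, dpn.memptr(), HW2 * n);
        for (int f = 0; f < F1; ++f)
          std::copy(dpn.colptr(f), dpn.colptr(f) + HW2,
                    DP.colptr(f) + HW2 * n);
      }
      // pool backward + leaky' -> DY1 (HW1*B x F1)
      arma::fmat DY1(r1, F1, arma::fill::zeros);
      for (int n = 0; n < B; ++n) {
        for (int f = 0; f < F1; ++f) {
          const float* dp = DP.colptr(f) + HW2 * n;
          const int* am = amax.data() + (HW2 * (f + (size_t)F1 * n));
          const float* a1p = A1.colptr(f) + HW1 * n;
          float* dy = DY1.colptr(f) + HW1 * n;
          for (size_t i = 0; i < HW2; ++i) {
            float g = dp[i];
            if (a1p[am[i]] < 0) g *= slope;
            dy[am[i]] += g;
          }
        }
      }
      arma::fmat dW1 = M1.t() * DY1;
      arma::fmat db1 = arma::sum(DY1, 0).t();

      sgd_step_f(W1, vW1, dW1, lr, mom, l2);
      sgd_step_f(b1, vb1, db1, lr, mom, 0.0f);
      sgd_step_f(W2, vW2, dW2, lr, mom, l2);
      sgd_step_f(b2, vb2, db2, lr, mom, 0.0f);
      sgd_step_f(W3, vW3, dW3, lr, mom, l2);
      sgd_step_f(b3, vb3, db3, lr, mom, 0.0f);
      sgd_step_f(W4, vW4, dW4, lr, mom, l2);
      sgd_step_f(b4, vb4, db4, lr, mom, 0.0f);
    }
    hist_loss[ep] = loss_sum / N;
    hist_acc[ep] = (double)correct / N;
  }

  auto back = [](const arma::fmat& m, IntegerVector dims) {
    NumericVector v(m.n_elem);
    for (arma::uword i = 0; i < m.n_elem; ++i) v[i] = (double)m.memptr()[i];
    if (dims.size() > 0) v.attr("dim") = dims;
    return v;
  };
  IntegerVector dW1d = IntegerVector::create(K, K, 3, F1);
  IntegerVector dW2d = IntegerVector::create(K, K, F1, F2);
  IntegerVector dW3d = IntegerVector::create(FC, flat);
  IntegerVector dW4d = IntegerVector::create(NC, FC);
  IntegerVector novec(0);
  return List::create(
    _["weights"] = List::create(
      _["W1"] = back(W1, dW1d), _["b1"] = back(b1, novec),
      _["W2"] = back(W2, dW2d), _["b2"] = back(b2, novec),
      _["W3"] = back(W3, dW3d), _["b3"] = back(b3, novec),
      _["W4"] = back(W4, dW4d), _["b4"] = back(b4, novec)),
    _["loss"] = hist_loss, _["accuracy"] = hist_acc);
}

// Round doubles to the nearest float32-representable value (weights are
// stored at float precision throughout).
// [[Rcpp::export]]
NumericVector cpp_float_round(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = (double)(float)x[i];
  out.attr("dim") = x.attr("dim");
  return out;
}
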