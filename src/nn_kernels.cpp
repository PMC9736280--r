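// Minimal convolutional-network kernels: zero-padded 2D convolution
// (im2col + GEMM), its gradients, and 2x2 max-pooling with argmax caching.
// Tensors are R arrays with dim = (H, W, C, N), column-major.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const double* x, int H, int W, int C, int k) {
  // rows: H*W output positions; cols: k*k*C taps. Zero padding, stride 1.
  const int pad = k / 2;
  arma::mat col(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* plane = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int cc = c * k * k + kj * k + ki;
        const int di = ki - pad, dj = kj - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i) {
            col(j * H + i, cc) = plane[(size_t)sj * H + (i + di)];
          }
        }
      }
    }
  }
  return col;
}

static void col2im_add(double* dx, const arma::mat& dcol, int H, int W, int C,
                       int k) {
  const int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    double* plane = dx + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int cc = c * k * k + kj * k + ki;
        const int di = ki - pad, dj = kj - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i) {
            plane[(size_t)sj * H + (i + di)] += dcol(j * H + i, cc);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericMatrix weight,
                                 NumericVector bias, int k) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = weight.ncol();
  arma::mat Wm(weight.begin(), weight.nrow(), Cout, false);
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k);
    arma::mat out = col * Wm;
    out.each_row() += arma::rowvec(bias.begin(), Cout, false);
    std::copy(out.begin(), out.end(), y.begin() + (size_t)n * H * W * Cout);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericMatrix weight,
                         NumericVector dy, int k) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = weight.ncol();
  arma::mat Wm(weight.begin(), weight.nrow(), Cout, false);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericMatrix dW(weight.nrow(), Cout);
  NumericVector db(Cout);
  arma::mat dWm(dW.begin(), weight.nrow(), Cout, false);
  arma::vec dbv(db.begin(), Cout, false);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k);
    arma::mat dyn(const_cast<double*>(dy.begin()) + (size_t)n * H * W * Cout,
                  H * W, Cout, false);
    dWm += col.t() * dyn;
    dbv += arma::sum(dyn, 0).t();
    arma::mat dcol = dyn * Wm.t();
    col2im_add(dx.begin() + (size_t)n * H * W * C, dcol, H, W, C, k);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // 0-based flat index into x
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * H * W;
      const size_t offo = ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double best = -1e300; size_t bi = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              size_t p = off + (size_t)(2 * j + dj) * H + (2 * i + di);
              if (x[p] > best) { best = x[p]; bi = p; }
            }
          }
          y[offo + (size_t)j * Ho + i] = best;
          idx[offo + (size_t)j * Ho + i] = (int)bi;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector idx,
                                   IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t p = 0; p < dy.size(); ++p) dx[idx[p]] += dy[p];
  return dx;
}

// Connected-component labeling of a binary mask (BFS, row-major discovery
// order so the first-found component among equal sizes has the smallest
// (row, col) starting pixel). connectivity is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int>> nb;
  nb.push_back({-1, 0}); nb.push_back({1, 0});
  nb.push_back({0, -1}); nb.push_back({0, 1});
  if (connectivity == 8) {
    nb.push_back({-1, -1}); nb.push_back({-1, 1});
    nb.push_back({1, -1}); nb.push_back({1, 1});
  }
  int next = 0;
  std::vector<int> qi, qj;
  for (int i = 0; i < H; ++i) {       // row-major scan
    for (int j = 0; j < W; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      qi.clear(); qj.clear();
      qi.push_back(i); qj.push_back(j);
      lab(i, j) = next;
      size_t head = 0;
      while (head < qi.size()) {
        int ci = qi[head], cj = qj[head]; ++head;
        for (auto& d : nb) {
          int ni = ci + d.first, nj = cj + d.second;
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            qi.push_back(ni); qj.push_back(nj);
          }
        }
      }
    }
  }
  return lab;
}

// ---- element-wise layer kernels (avoid repeated channel broadcasting in R) --

// Per-channel sums and sums of squares over (H, W, N).
// [[Rcpp::export]]
NumericMatrix cpp_channel_stats(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericMatrix out(2, C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)n * C + c) * hw;
      double s = 0, s2 = 0;
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      out(0, c) += s; out(1, c) += s2;
    }
  }
  return out;
}

// y = x * scale[c] + shift[c]
// [[Rcpp::export]]
NumericVector cpp_scale_shift(NumericVector x, NumericVector scale,
                              NumericVector shift) {
  IntegerVector d = x.attr("dim");
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)n * C + c) * hw;
      double* q = y.begin() + ((size_t)n * C + c) * hw;
      const double a = scale[c], b = shift[c];
      for (size_t i = 0; i < hw; ++i) q[i] = p[i] * a + b;
    }
  }
  return y;
}

// Batch-norm backward: xhat recomputed from x; returns dx, dgamma, dbeta.
// [[Rcpp::export]]
List cpp_bn_backward(NumericVector dy, NumericVector x, NumericVector mean,
                     NumericVector inv_sd, NumericVector gamma,
                     bool batch_stats) {
  IntegerVector d = x.attr("dim");
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  const double M = (double)hw * N;
  NumericVector dgamma(C), dbeta(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* px = x.begin() + ((size_t)n * C + c) * hw;
      const double* pd = dy.begin() + ((size_t)n * C + c) * hw;
      const double mu = mean[c], is = inv_sd[c];
      double sg = 0, sb = 0;
      for (size_t i = 0; i < hw; ++i) {
        sg += pd[i] * (px[i] - mu) * is;
        sb += pd[i];
      }
      dgamma[c] += sg; dbeta[c] += sb;
    }
  }
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* px = x.begin() + ((size_t)n * C + c) * hw;
      const double* pd = dy.begin() + ((size_t)n * C + c) * hw;
      double* q = dx.begin() + ((size_t)n * C + c) * hw;
      const double mu = mean[c], is = inv_sd[c], sc = gamma[c] * is;
      const double a = batch_stats ? dbeta[c] / M : 0.0;
      const double b = batch_stats ? dgamma[c] / M : 0.0;
      for (size_t i = 0; i < hw; ++i) {
        q[i] = sc * (pd[i] - a - (px[i] - mu) * is * b);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_prelu_forward(NumericVector x, NumericVector alpha) {
  IntegerVector d = x.attr("dim");
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((size_t)n * C + c) * hw;
      double* q = y.begin() + ((size_t)n * C + c) * hw;
      const double a = alpha[c];
      for (size_t i = 0; i < hw; ++i) q[i] = p[i] > 0 ? p[i] : a * p[i];
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_prelu_backward(NumericVector dy, NumericVector x, NumericVector alpha) {
  IntegerVector d = x.attr("dim");
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  NumericVector dalpha(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* px = x.begin() + ((size_t)n * C + c) * hw;
      const double* pd = dy.begin() + ((size_t)n * C + c) * hw;
      double* q = dx.begin() + ((size_t)n * C + c) * hw;
      const double a = alpha[c];
      double da = 0;
      for (size_t i = 0; i < hw; ++i) {
        if (px[i] > 0) q[i] = pd[i];
        else { q[i] = a * pd[i]; da += pd[i] * px[i]; }
      }
      dalpha[c] += da;
    }
  }
  return List::create(_["dx"] = dx, _["dalpha"] = dalpha);
}
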