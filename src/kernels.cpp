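// Numeric kernels: 2D convolution (im2col + GEMM), max pooling, and an
// exact anisotropic squared Euclidean distance transform.
//
// Array layout conventions (R column-major):
//   activations x: (H, W, C, N)   index i + H*(j + W*(c + C*n))
//   conv weights w: (KH, KW, Cin, Cout)
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_extent(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Build the transposed im2col matrix C (L x K), L = Ho*Wo, K = KH*KW*Cin,
// for image n of x. Out-of-bounds taps are zero.
static void im2col_block(const double* x, int H, int W, int Cin,
                         int KH, int KW, int stride, int pad,
                         int Ho, int Wo, arma::mat& C, int row0) {
  const int L = Ho * Wo;
  (void)L;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < KW; ++kj) {
      for (int ki = 0; ki < KH; ++ki) {
        const int r = ki + KH * (kj + KW * c);
        double* col = C.colptr(r) + row0;
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride - pad + kj;
          double* cl = col + (size_t)Ho * oj;
          if (j < 0 || j >= W) {
            for (int oi = 0; oi < Ho; ++oi) cl[oi] = 0.0;
            continue;
          }
          const double* xcj = xc + (size_t)H * j;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride - pad + ki;
            cl[oi] = (i < 0 || i >= H) ? 0.0 : xcj[i];
          }
        }
      }
    }
  }
}

// Scatter-add of a column-gradient matrix G (L x K) back onto an image.
static void col2im_block(const arma::mat& G, int row0, int H, int W,
                         int Cin, int KH, int KW, int stride, int pad,
                         int Ho, int Wo, double* gx) {
  for (int c = 0; c < Cin; ++c) {
    double* xc = gx + (size_t)H * W * c;
    for (int kj = 0; kj < KW; ++kj) {
      for (int ki = 0; ki < KH; ++ki) {
        const int r = ki + KH * (kj + KW * c);
        const double* col = G.colptr(r) + row0;
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          double* xcj = xc + (size_t)H * j;
          const double* cl = col + (size_t)Ho * oj;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride - pad + ki;
            if (i < 0 || i >= H) continue;
            xcj[i] += cl[oi];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            NumericVector bias, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int KH = wdim[0], KW = wdim[1], Cout = wdim[3];
  const int Ho = out_extent(H, KH, stride, pad);
  const int Wo = out_extent(W, KW, stride, pad);
  const int K = KH * KW * Cin, L = Ho * Wo;
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector y((size_t)L * Cout * N);
  arma::mat C(L, K);
  for (int n = 0; n < N; ++n) {
    im2col_block(x.begin() + (size_t)H * W * Cin * n, H, W, Cin,
                 KH, KW, stride, pad, Ho, Wo, C, 0);
    arma::mat Y(y.begin() + (size_t)L * Cout * n, L, Cout, false, true);
    Y = C * Wm;
    if (bias.size() == Cout)
      for (int co = 0; co < Cout; ++co) Y.col(co) += bias[co];
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, IntegerVector xdim,
                   NumericVector w, IntegerVector wdim,
                   NumericVector gy, int stride, int pad,
                   bool need_gx, bool need_gw) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int KH = wdim[0], KW = wdim[1], Cout = wdim[3];
  const int Ho = out_extent(H, KH, stride, pad);
  const int Wo = out_extent(W, KW, stride, pad);
  const int K = KH * KW * Cin, L = Ho * Wo;
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector gx(need_gx ? (size_t)H * W * Cin * N : 0);
  NumericVector gw((size_t)K * Cout);
  NumericVector gb(Cout);
  arma::mat Gw(gw.begin(), K, Cout, false, true);
  arma::mat C(L, K), Gcol;
  for (int n = 0; n < N; ++n) {
    const arma::mat G(const_cast<double*>(gy.begin()) + (size_t)L * Cout * n,
                      L, Cout, false, true);
    if (need_gw || need_gx)
      im2col_block(x.begin() + (size_t)H * W * Cin * n, H, W, Cin,
                   KH, KW, stride, pad, Ho, Wo, C, 0);
    if (need_gw) Gw += C.t() * G;
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(G.col(co));
    if (need_gx) {
      Gcol = G * Wm.t();
      col2im_block(Gcol, 0, H, W, Cin, KH, KW, stride, pad, Ho, Wo,
                   gx.begin() + (size_t)H * W * Cin * n);
    }
  }
  if (need_gx) gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, IntegerVector xdim,
                    int ksize, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = out_extent(H, ksize, stride, pad);
  const int Wo = out_extent(W, ksize, stride, pad);
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector arg((size_t)Ho * Wo * C * N);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int oj = 0; oj < Wo; ++oj) {
        for (int oi = 0; oi < Ho; ++oi) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          for (int kj = 0; kj < ksize; ++kj) {
            const int j = oj * stride - pad + kj;
            if (j < 0 || j >= W) continue;
            for (int ki = 0; ki < ksize; ++ki) {
              const int i = oi * stride - pad + ki;
              if (i < 0 || i >= H) continue;
              const double v = xc[i + (size_t)H * j];
              if (v > best) { best = v; bi = i + H * j; }
            }
          }
          // column-major output order must be (oi fastest): index directly
          const size_t oidx = (size_t)oi + Ho * ((size_t)oj + Wo * (c + (size_t)C * n));
          y[oidx] = best;
          arg[oidx] = bi;
          (void)o;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector gy, IntegerVector arg,
                             IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector gx((size_t)H * W * C * N);
  const size_t plane = (size_t)H * W;
  const size_t n_out = gy.size();
  const size_t per_img = n_out / ((size_t)C * N) * 1; // Ho*Wo
  size_t idx = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* gxc = gx.begin() + plane * (c + (size_t)C * n);
      for (size_t l = 0; l < per_img; ++l, ++idx) {
        const int bi = arg[idx];
        if (bi >= 0) gxc[bi] += gy[idx];
      }
    }
  }
  gx.attr("dim") = xdim;
  return gx;
}

// ---- exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
// generalized to a uniform physical sample spacing per axis -----------------

static const double DT_BIG = 1e20;

static void dt1d(const double* f, double* d, int n, double s,
                 int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_BIG;
  z[1] = DT_BIG;
  for (int q = 1; q < n; ++q) {
    const double xq = q * s, fq = f[q];
    while (true) {
      const double xv = v[k] * s;
      const double sep = (fq + xq * xq - (f[v[k]] + xv * xv)) /
                         (2.0 * xq - 2.0 * xv);
      if (sep <= z[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = sep;
        z[k + 1] = DT_BIG;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * s;
    while (z[k + 1] < xq) ++k;
    const double dv = xq - v[k] * s;
    d[q] = dv * dv + f[v[k]];
  }
}

// Squared physical distance from every voxel to the nearest foreground voxel
// centre. mask: (n1, n2, n3) column-major, foreground > 0.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(NumericVector mask, IntegerVector mdim,
                         NumericVector spacing) {
  const int n1 = mdim[0], n2 = mdim[1], n3 = mdim[2];
  const size_t nv = (size_t)n1 * n2 * n3;
  NumericVector d(nv);
  for (size_t i = 0; i < nv; ++i) d[i] = mask[i] > 0 ? 0.0 : DT_BIG;
  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 1 (stride 1)
  for (int k3 = 0; k3 < n3; ++k3)
    for (int k2 = 0; k2 < n2; ++k2) {
      double* col = d.begin() + (size_t)n1 * (k2 + (size_t)n2 * k3);
      dt1d(col, dd.data(), n1, spacing[0], v.data(), z.data());
      std::copy(dd.begin(), dd.begin() + n1, col);
    }
  // axis 2 (stride n1)
  for (int k3 = 0; k3 < n3; ++k3)
    for (int k1 = 0; k1 < n1; ++k1) {
      double* base = d.begin() + (size_t)k1 + (size_t)n1 * n2 * k3;
      for (int k2 = 0; k2 < n2; ++k2) f[k2] = base[(size_t)n1 * k2];
      dt1d(f.data(), dd.data(), n2, spacing[1], v.data(), z.data());
      for (int k2 = 0; k2 < n2; ++k2) base[(size_t)n1 * k2] = dd[k2];
    }
  // axis 3 (stride n1*n2)
  const size_t s3 = (size_t)n1 * n2;
  for (int k2 = 0; k2 < n2; ++k2)
    for (int k1 = 0; k1 < n1; ++k1) {
      double* base = d.begin() + (size_t)k1 + (size_t)n1 * k2;
      for (int k3 = 0; k3 < n3; ++k3) f[k3] = base[s3 * k3];
      dt1d(f.data(), dd.data(), n3, spacing[2], v.data(), z.data());
      for (int k3 = 0; k3 < n3; ++k3) base[s3 * k3] = dd[k3];
    }
  d.attr("dim") = mdim;
  return d;
}

// ---- batch normalization on (H, W, C, N) layout ---------------------------

// [[Rcpp::export]]
List cpp_bn_fw(NumericVector x, IntegerVector xdim, NumericVector gamma,
               NumericVector beta, NumericVector mu_in, NumericVector var_in,
               bool training, double eps) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t plane = (size_t)H * W;
  NumericVector y(x.size());
  NumericVector mu(C), var(C);
  const double m = (double)plane * N;
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, ss = 0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + plane * (c + (size_t)C * n);
        for (size_t i = 0; i < plane; ++i) { s += xc[i]; }
      }
      const double mc = s / m;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + plane * (c + (size_t)C * n);
        for (size_t i = 0; i < plane; ++i) {
          const double d = xc[i] - mc; ss += d * d;
        }
      }
      mu[c] = mc;
      var[c] = ss / m;
    }
  } else {
    mu = clone(mu_in);
    var = clone(var_in);
  }
  for (int c = 0; c < C; ++c) {
    const double invstd = 1.0 / std::sqrt(var[c] + eps);
    const double a = gamma[c] * invstd;
    const double b = beta[c] - a * mu[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      double* yc = y.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) yc[i] = a * xc[i] + b;
    }
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
List cpp_bn_bw(NumericVector x, IntegerVector xdim, NumericVector gamma,
               NumericVector mu, NumericVector var, NumericVector gy,
               bool training, double eps) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;
  NumericVector gx(x.size()), ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    const double invstd = 1.0 / std::sqrt(var[c] + eps);
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* gc = gy.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        sg += gc[i];
        sgx += gc[i] * (xc[i] - mu[c]) * invstd;
      }
    }
    ggamma[c] = sgx;
    gbeta[c] = sg;
    const double a = gamma[c] * invstd;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* gc = gy.begin() + plane * (c + (size_t)C * n);
      double* oc = gx.begin() + plane * (c + (size_t)C * n);
      if (training) {
        for (size_t i = 0; i < plane; ++i) {
          const double xhat = (xc[i] - mu[c]) * invstd;
          oc[i] = a * (gc[i] - (sg + xhat * sgx) / m);
        }
      } else {
        for (size_t i = 0; i < plane; ++i) oc[i] = a * gc[i];
      }
    }
  }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// fused elementwise helpers to avoid R-level allocations in hot paths

// [[Rcpp::export]]
List cpp_relu_fw(NumericVector x) {
  NumericVector y(x.size());
  LogicalVector keep(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const bool k = x[i] > 0;
    keep[i] = k;
    y[i] = k ? x[i] : 0.0;
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["keep"] = keep);
}

// [[Rcpp::export]]
NumericVector cpp_mask_mul(NumericVector g, LogicalVector keep) {
  NumericVector out(g.size());
  for (R_xlen_t i = 0; i < g.size(); ++i) out[i] = keep[i] ? g[i] : 0.0;
  out.attr("dim") = g.attr("dim");
  return out;
}

// fused batchnorm + optional ReLU (single pass over the activation tensor)

// [[Rcpp::export]]
List cpp_bnact_fw(NumericVector x, IntegerVector xdim, NumericVector gamma,
                  NumericVector beta, NumericVector mu_in,
                  NumericVector var_in, bool training, double eps,
                  bool relu) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t plane = (size_t)H * W;
  NumericVector y(x.size());
  NumericVector mu(C), var(C);
  const double m = (double)plane * N;
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, ss = 0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + plane * (c + (size_t)C * n);
        for (size_t i = 0; i < plane; ++i) s += xc[i];
      }
      const double mc = s / m;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + plane * (c + (size_t)C * n);
        for (size_t i = 0; i < plane; ++i) {
          const double d = xc[i] - mc; ss += d * d;
        }
      }
      mu[c] = mc; var[c] = ss / m;
    }
  } else {
    mu = clone(mu_in); var = clone(var_in);
  }
  for (int c = 0; c < C; ++c) {
    const double invstd = 1.0 / std::sqrt(var[c] + eps);
    const double a = gamma[c] * invstd;
    const double b = beta[c] - a * mu[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      double* yc = y.begin() + plane * (c + (size_t)C * n);
      if (relu)
        for (size_t i = 0; i < plane; ++i) {
          const double v = a * xc[i] + b;
          yc[i] = v > 0 ? v : 0.0;
        }
      else
        for (size_t i = 0; i < plane; ++i) yc[i] = a * xc[i] + b;
    }
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["mu"] = mu, _["var"] = var);
}

// backward of fused bn(+relu); y is the forward output (for the relu mask)
// [[Rcpp::export]]
List cpp_bnact_bw(NumericVector x, IntegerVector xdim, NumericVector gamma,
                  NumericVector mu, NumericVector var, NumericVector y,
                  NumericVector gy, bool training, double eps, bool relu) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;
  NumericVector gx(x.size()), ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    const double invstd = 1.0 / std::sqrt(var[c] + eps);
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* yc = y.begin() + plane * (c + (size_t)C * n);
      const double* gc = gy.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        const double g = (relu && yc[i] <= 0) ? 0.0 : gc[i];
        sg += g;
        sgx += g * (xc[i] - mu[c]) * invstd;
      }
    }
    ggamma[c] = sgx;
    gbeta[c] = sg;
    const double a = gamma[c] * invstd;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + plane * (c + (size_t)C * n);
      const double* yc = y.begin() + plane * (c + (size_t)C * n);
      const double* gc = gy.begin() + plane * (c + (size_t)C * n);
      double* oc = gx.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) {
        const double g = (relu && yc[i] <= 0) ? 0.0 : gc[i];
        if (training) {
          const double xhat = (xc[i] - mu[c]) * invstd;
          oc[i] = a * (g - (sg + xhat * sgx) / m);
        } else {
          oc[i] = a * g;
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// residual add + relu fused: y = relu(a + b)
// [[Rcpp::export]]
NumericVector cpp_addrelu_fw(NumericVector a, NumericVector b) {
  NumericVector y(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    const double v = a[i] + b[i];
    y[i] = v > 0 ? v : 0.0;
  }
  y.attr("dim") = a.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_addrelu_bw(NumericVector y, NumericVector gy) {
  NumericVector g(y.size());
  for (R_xlen_t i = 0; i < y.size(); ++i) g[i] = y[i] > 0 ? gy[i] : 0.0;
  g.attr("dim") = y.attr("dim");
  return g;
}
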