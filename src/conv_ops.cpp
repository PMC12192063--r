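// Minimal CPU kernels for the neural-network core.
// Tensor layout everywhere: R arrays with dim = c(H, W, C, N) (column-major),
// weights dim = c(kh, kw, Cin/groups, Cout). Stride is always 1; "same"
// padding is supplied by the caller (pad = (k-1)/2 for odd k).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat im2col_one(const double* x, int H, int W, int C0,
                                   int c_off, int Cg, int kh, int kw, int pad) {
  // rows: ki + kh*(kj + kw*cl), cols: ho + H*wo  (same-size output)
  arma::mat col(kh * kw * Cg, H * W, arma::fill::zeros);
  for (int cl = 0; cl < Cg; ++cl) {
    const double* xc = x + (size_t)(c_off + cl) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * cl);
        for (int wo = 0; wo < W; ++wo) {
          int wi = wo + kj - pad;
          if (wi < 0 || wi >= W) continue;
          double* dst = col.colptr(0) + r; // use explicit indexing below
          for (int ho = 0; ho < H; ++ho) {
            int hi = ho + ki - pad;
            if (hi < 0 || hi >= H) continue;
            col(r, ho + H * wo) = xc[hi + H * wi];
          }
          (void)dst;
        }
      }
    }
  }
  (void)C0;
  return col;
}

static inline void col2im_one(const arma::mat& dcol, double* dx, int H, int W,
                              int c_off, int Cg, int kh, int kw, int pad) {
  for (int cl = 0; cl < Cg; ++cl) {
    double* xc = dx + (size_t)(c_off + cl) * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * cl);
        for (int wo = 0; wo < W; ++wo) {
          int wi = wo + kj - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < H; ++ho) {
            int hi = ho + ki - pad;
            if (hi < 0 || hi >= H) continue;
            xc[hi + H * wi] += dcol(r, ho + H * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw_cpp")]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector w, NumericVector b,
                            int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  if (C != Cg * groups) stop("input channels (%d) != kernel channels*groups (%d)", C, Cg * groups);
  if (Cout % groups != 0) stop("output channels not divisible by groups");
  int Coutg = Cout / groups;
  NumericVector y(static_cast<R_xlen_t>(H) * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);

  // weight matrices per group: Coutg x (kh*kw*Cg)
  std::vector<arma::mat> Wg(groups);
  for (int g = 0; g < groups; ++g) {
    arma::mat Wm(Coutg, kh * kw * Cg);
    for (int nl = 0; nl < Coutg; ++nl) {
      int n = g * Coutg + nl;
      for (int cl = 0; cl < Cg; ++cl)
        for (int kj = 0; kj < kw; ++kj)
          for (int ki = 0; ki < kh; ++ki)
            Wm(nl, ki + kh * (kj + kw * cl)) =
                w[ki + kh * (kj + kw * ((size_t)cl + Cg * n))];
    }
    Wg[g] = Wm;
  }

  for (int s = 0; s < N; ++s) {
    const double* xs = x.begin() + (size_t)s * H * W * C;
    double* ys = y.begin() + (size_t)s * H * W * Cout;
    for (int g = 0; g < groups; ++g) {
      arma::mat col = im2col_one(xs, H, W, C, g * Cg, Cg, kh, kw, pad);
      arma::mat Y = Wg[g] * col; // Coutg x HW
      for (int nl = 0; nl < Coutg; ++nl) {
        int n = g * Coutg + nl;
        double bias = b.size() ? b[n] : 0.0;
        double* yc = ys + (size_t)n * H * W;
        for (int p = 0; p < H * W; ++p) yc[p] = Y(nl, p) + bias;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw_cpp")]]
List conv2d_bw_cpp(NumericVector x, NumericVector w, NumericVector dy,
                   int pad, int groups, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  int Coutg = Cout / groups;

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);

  std::vector<arma::mat> Wg(groups), dWg(groups, arma::mat(Coutg, kh * kw * Cg, arma::fill::zeros));
  for (int g = 0; g < groups; ++g) {
    arma::mat Wm(Coutg, kh * kw * Cg);
    for (int nl = 0; nl < Coutg; ++nl) {
      int n = g * Coutg + nl;
      for (int cl = 0; cl < Cg; ++cl)
        for (int kj = 0; kj < kw; ++kj)
          for (int ki = 0; ki < kh; ++ki)
            Wm(nl, ki + kh * (kj + kw * ((size_t)cl))) =
                w[ki + kh * (kj + kw * ((size_t)cl + Cg * n))];
    }
    Wg[g] = Wm;
  }

  for (int s = 0; s < N; ++s) {
    const double* xs = x.begin() + (size_t)s * H * W * C;
    const double* dys = dy.begin() + (size_t)s * H * W * Cout;
    double* dxs = dx.begin() + (size_t)s * H * W * C;
    for (int g = 0; g < groups; ++g) {
      arma::mat col = im2col_one(xs, H, W, C, g * Cg, Cg, kh, kw, pad);
      arma::mat dY(Coutg, H * W);
      for (int nl = 0; nl < Coutg; ++nl) {
        int n = g * Coutg + nl;
        const double* dyc = dys + (size_t)n * H * W;
        for (int p = 0; p < H * W; ++p) dY(nl, p) = dyc[p];
        if (has_bias) {
          double acc = 0.0;
          for (int p = 0; p < H * W; ++p) acc += dyc[p];
          db[n] += acc;
        }
      }
      dWg[g] += dY * col.t();
      arma::mat dcol = Wg[g].t() * dY;
      col2im_one(dcol, dxs, H, W, g * Cg, Cg, kh, kw, pad);
    }
  }

  for (int g = 0; g < groups; ++g)
    for (int nl = 0; nl < Coutg; ++nl) {
      int n = g * Coutg + nl;
      for (int cl = 0; cl < Cg; ++cl)
        for (int kj = 0; kj < kw; ++kj)
          for (int ki = 0; ki < kh; ++ki)
            dw[ki + kh * (kj + kw * ((size_t)cl + Cg * n))] =
                dWg[g](nl, ki + kh * (kj + kw * cl));
    }

  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_fw_cpp")]]
List maxpool2_fw_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2 requires even H and W");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector idx(y.size()); // linear index into the input plane
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t q = 0;
  for (int s = 0; s < N; ++s)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + ((size_t)s * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          int best = -1;
          double bv = -1e300;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              int p = (2 * ho + di) + H * (2 * wo + dj);
              if (xp[p] > bv) { bv = xp[p]; best = p; }
            }
          // y is laid out (Ho,Wo) within (c,s) but we iterate wo outer, ho inner
          size_t pos = (size_t)(ho + Ho * wo) + ((size_t)s * C + c) * Ho * Wo;
          y[pos] = bv;
          idx[pos] = best;
          ++q;
        }
    }
  (void)q;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw_cpp")]]
NumericVector maxpool2_bw_cpp(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int s = 0; s < N; ++s)
    for (int c = 0; c < C; ++c) {
      double* dxp = dx.begin() + ((size_t)s * C + c) * H * W;
      const size_t off = ((size_t)s * C + c) * Ho * Wo;
      for (int p = 0; p < Ho * Wo; ++p) dxp[idx[off + p]] += dy[off + p];
    }
  return dx;
}

// [[Rcpp::export(name = ".upsample2_fw_cpp")]]
NumericVector upsample2_fw_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int s = 0; s < N; ++s)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + ((size_t)s * C + c) * H * W;
      double* yp = y.begin() + ((size_t)s * C + c) * Ho * Wo;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double v = xp[h + H * w];
          yp[2 * h + Ho * (2 * w)] = v;
          yp[2 * h + 1 + Ho * (2 * w)] = v;
          yp[2 * h + Ho * (2 * w + 1)] = v;
          yp[2 * h + 1 + Ho * (2 * w + 1)] = v;
        }
    }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bw_cpp")]]
NumericVector upsample2_bw_cpp(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  int H = Ho / 2, W = Wo / 2;
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int s = 0; s < N; ++s)
    for (int c = 0; c < C; ++c) {
      const double* dyp = dy.begin() + ((size_t)s * C + c) * Ho * Wo;
      double* dxp = dx.begin() + ((size_t)s * C + c) * H * W;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          dxp[h + H * w] = dyp[2 * h + Ho * (2 * w)] + dyp[2 * h + 1 + Ho * (2 * w)] +
                           dyp[2 * h + Ho * (2 * w + 1)] + dyp[2 * h + 1 + Ho * (2 * w + 1)];
    }
  return dx;
}
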