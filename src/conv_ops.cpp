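// Hot loops of the CNN engine: im2col / col2im patch (un)packing and 2x2
// max pooling on channel-first (C, H, W, N) activations. Matrix products
// stay on the R side (BLAS). All layouts are column-major and match the
// ordering conventions in R/nnet.R: patch elements are (c, dy, dx) with c
// fastest; positions are column-major over (Ho, Wo), then image index.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector A, int C, int H, int W, int N, int k) {
  const int Ho = H - k + 1, Wo = W - k + 1;
  const int kkC = k * k * C, npos = Ho * Wo;
  const R_xlen_t chw = (R_xlen_t)C * H * W;
  NumericMatrix P(kkC, (R_xlen_t)npos * N);
  const double* a = A.begin();
  double* p = P.begin();
  for (int n = 0; n < N; ++n) {
    const double* an = a + n * chw;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        double* col = p + ((R_xlen_t)n * npos + (R_xlen_t)ox * Ho + oy) * kkC;
        for (int dx = 0; dx < k; ++dx) {
          const double* src = an + (R_xlen_t)(ox + dx) * C * H + (R_xlen_t)oy * C;
          for (int dy = 0; dy < k; ++dy) {
            const double* s = src + (R_xlen_t)dy * C;
            for (int c = 0; c < C; ++c) *col++ = s[c];
          }
        }
      }
    }
  }
  return P;
}

// Scatter-add of patch gradients back onto the input: inverse of cpp_im2col.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dP, int C, int H, int W, int N, int k) {
  const int Ho = H - k + 1, Wo = W - k + 1;
  const int kkC = k * k * C, npos = Ho * Wo;
  const R_xlen_t chw = (R_xlen_t)C * H * W;
  NumericVector dA((R_xlen_t)chw * N);
  const double* p = dP.begin();
  double* a = dA.begin();
  for (int n = 0; n < N; ++n) {
    double* an = a + n * chw;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        const double* col = p + ((R_xlen_t)n * npos + (R_xlen_t)ox * Ho + oy) * kkC;
        for (int dx = 0; dx < k; ++dx) {
          double* dst = an + (R_xlen_t)(ox + dx) * C * H + (R_xlen_t)oy * C;
          for (int dy = 0; dy < k; ++dy) {
            double* d = dst + (R_xlen_t)dy * C;
            for (int c = 0; c < C; ++c) d[c] += *col++;
          }
        }
      }
    }
  }
  return dA;
}

// Separable Gaussian blur of an H x W matrix (replicate padding).
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix G, double sigma) {
  const int H = G.nrow(), W = G.ncol();
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  NumericMatrix T(H, W), out(H, W);
  for (int x = 0; x < W; ++x) {          // vertical pass
    for (int y = 0; y < H; ++y) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) {
        int yy = y + i;
        if (yy < 0) yy = 0; else if (yy >= H) yy = H - 1;
        acc += k[i + r] * G(yy, x);
      }
      T(y, x) = acc;
    }
  }
  for (int x = 0; x < W; ++x) {          // horizontal pass
    for (int y = 0; y < H; ++y) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) {
        int xx = x + i;
        if (xx < 0) xx = 0; else if (xx >= W) xx = W - 1;
        acc += k[i + r] * T(y, xx);
      }
      out(y, x) = acc;
    }
  }
  return out;
}

// 2x2 max pool (stride 2, odd trailing row/col dropped). Returns the pooled
// values and the argmax code (1..4 in (y,x) = (0,0),(0,1),(1,0),(1,1) order,
// first wins on ties) for gradient routing.
// [[Rcpp::export]]
List cpp_pool_fwd(NumericVector A, int C, int H, int W, int N) {
  const int H2 = H / 2, W2 = W / 2;
  const R_xlen_t chw = (R_xlen_t)C * H * W, ohw = (R_xlen_t)C * H2 * W2;
  NumericVector out(ohw * N);
  IntegerVector code(ohw * N);
  const double* a = A.begin();
  double* o = out.begin();
  int* q = code.begin();
  for (int n = 0; n < N; ++n) {
    const double* an = a + n * chw;
    for (int x = 0; x < W2; ++x) {
      for (int y = 0; y < H2; ++y) {
        const double* p00 = an + (R_xlen_t)(2 * x) * C * H + (R_xlen_t)(2 * y) * C;
        const double* p10 = p00 + C;                       // y+1
        const double* p01 = p00 + (R_xlen_t)C * H;         // x+1
        const double* p11 = p01 + C;
        double* oo = o + n * ohw + (R_xlen_t)x * C * H2 + (R_xlen_t)y * C;
        int* qq = q + n * ohw + (R_xlen_t)x * C * H2 + (R_xlen_t)y * C;
        for (int c = 0; c < C; ++c) {
          double v = p00[c]; int w = 1;
          if (p01[c] > v) { v = p01[c]; w = 2; }
          if (p10[c] > v) { v = p10[c]; w = 3; }
          if (p11[c] > v) { v = p11[c]; w = 4; }
          oo[c] = v; qq[c] = w;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["code"] = code);
}

// [[Rcpp::export]]
NumericVector cpp_pool_bwd(NumericVector dOut, IntegerVector code,
                           int C, int H, int W, int N) {
  const int H2 = H / 2, W2 = W / 2;
  const R_xlen_t chw = (R_xlen_t)C * H * W, ohw = (R_xlen_t)C * H2 * W2;
  NumericVector dA(chw * N);
  const double* g = dOut.begin();
  const int* q = code.begin();
  double* a = dA.begin();
  for (int n = 0; n < N; ++n) {
    double* an = a + n * chw;
    for (int x = 0; x < W2; ++x) {
      for (int y = 0; y < H2; ++y) {
        const R_xlen_t off = n * ohw + (R_xlen_t)x * C * H2 + (R_xlen_t)y * C;
        const double* gg = g + off;
        const int* qq = q + off;
        double* p00 = an + (R_xlen_t)(2 * x) * C * H + (R_xlen_t)(2 * y) * C;
        for (int c = 0; c < C; ++c) {
          switch (qq[c]) {
          case 1: p00[c] += gg[c]; break;
          case 2: p00[(R_xlen_t)C * H + c] += gg[c]; break;
          case 3: p00[C + c] += gg[c]; break;
          default: p00[(R_xlen_t)C * H + C + c] += gg[c];
          }
        }
      }
    }
  }
  return dA;
}
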