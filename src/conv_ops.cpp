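#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Column-major image layout throughout: x[r + H*(c + W*ch)], matching an
// R array of dim c(H, W, C). Output pixels are likewise ordered row-fastest
// so that matrix results reshape directly with array(., c(Ho, Wo, Cout)).

static inline int out_extent(int n, int k, int stride, int pad, int dil) {
  return (n + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride, int pad, int dil) {
  const int Ho = out_extent(H, kh, stride, pad, dil);
  const int Wo = out_extent(W, kw, stride, pad, dil);
  NumericMatrix out(Ho * Wo, kh * kw * C);  // zero-initialised
  const bool unit = (stride == 1 && dil == 1);
  for (int ch = 0; ch < C; ++ch) {
    for (int kc = 0; kc < kw; ++kc) {
      for (int kr = 0; kr < kh; ++kr) {
        const int col = kr + kh * (kc + kw * ch);
        double *dst = &out(0, col);
        for (int oc = 0; oc < Wo; ++oc) {
          const int ic = oc * stride - pad + kc * dil;
          if (ic < 0 || ic >= W) { dst += Ho; continue; }
          const double *src = &x[H * (ic + (R_xlen_t)W * ch)];
          if (unit) {
            // contiguous run: ir = orr - pad + kr valid for
            // orr in [max(0, pad-kr), min(Ho, H+pad-kr))
            const int r0 = std::max(0, pad - kr);
            const int r1 = std::min(Ho, H + pad - kr);
            if (r1 > r0) {
              std::memcpy(dst + r0, src + (r0 - pad + kr),
                          (size_t)(r1 - r0) * sizeof(double));
            }
          } else {
            for (int orr = 0; orr < Ho; ++orr) {
              const int ir = orr * stride - pad + kr * dil;
              dst[orr] = (ir >= 0 && ir < H) ? src[ir] : 0.0;
            }
          }
          dst += Ho;
        }
      }
    }
  }
  return out;
}

// cols: (Ho*Wo) x (kh*kw*C) gradient w.r.t. im2col output; scatter-add back
// to an H x W x C gradient image.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int stride, int pad, int dil) {
  const int Ho = out_extent(H, kh, stride, pad, dil);
  const int Wo = out_extent(W, kw, stride, pad, dil);
  NumericVector out((R_xlen_t)H * W * C);
  const bool unit = (stride == 1 && dil == 1);
  for (int ch = 0; ch < C; ++ch) {
    for (int kc = 0; kc < kw; ++kc) {
      for (int kr = 0; kr < kh; ++kr) {
        const int col = kr + kh * (kc + kw * ch);
        const double *src = &cols(0, col);
        for (int oc = 0; oc < Wo; ++oc) {
          const int ic = oc * stride - pad + kc * dil;
          if (ic < 0 || ic >= W) { src += Ho; continue; }
          double *dst = &out[H * (ic + (R_xlen_t)W * ch)];
          if (unit) {
            const int r0 = std::max(0, pad - kr);
            const int r1 = std::min(Ho, H + pad - kr);
            double *d = dst + (r0 - pad + kr);
            for (int orr = r0; orr < r1; ++orr) *d++ += src[orr];
          } else {
            for (int orr = 0; orr < Ho; ++orr) {
              const int ir = orr * stride - pad + kr * dil;
              if (ir >= 0 && ir < H) dst[ir] += src[orr];
            }
          }
          src += Ho;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// 2x2 max pooling with stride 2; H and W must be even. Returns the pooled
// map plus 1-based linear argmax indices into the input for the backward
// scatter.
// [[Rcpp::export]]
List maxpool2_cpp(NumericVector x, int H, int W, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C);
  IntegerVector amax((R_xlen_t)Ho * Wo * C);
  for (int ch = 0; ch < C; ++ch) {
    const R_xlen_t xo = (R_xlen_t)H * W * ch;
    const R_xlen_t oo = (R_xlen_t)Ho * Wo * ch;
    for (int oc = 0; oc < Wo; ++oc) {
      for (int orr = 0; orr < Ho; ++orr) {
        const int r0 = 2 * orr, c0 = 2 * oc;
        R_xlen_t best = xo + r0 + (R_xlen_t)H * c0;
        double bv = x[best];
        const R_xlen_t cand[3] = {
          xo + (r0 + 1) + (R_xlen_t)H * c0,
          xo + r0 + (R_xlen_t)H * (c0 + 1),
          xo + (r0 + 1) + (R_xlen_t)H * (c0 + 1)};
        for (int k = 0; k < 3; ++k) {
          if (x[cand[k]] > bv) { bv = x[cand[k]]; best = cand[k]; }
        }
        out[oo + orr + (R_xlen_t)Ho * oc] = bv;
        amax[oo + orr + (R_xlen_t)Ho * oc] = (int)(best + 1);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["value"] = out, _["argmax"] = amax);
}
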