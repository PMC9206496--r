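#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Gather 3x3 neighbourhoods ("same" zero padding) of an (h, w, c)
// column-major array into an (h*w) x (9*c) matrix so that convolution
// becomes a single BLAS matrix product. Offset order within a channel
// block: k = (dx + 1) * 3 + (dy + 1), dy = row offset, dx = column offset.
// [[Rcpp::export]]
NumericMatrix im2col3x3_cpp(NumericVector x, int h, int w, int c) {
  NumericMatrix out(h * w, 9 * c); // zero-initialized
  const double* px = REAL(x);
  double* po = REAL(out);
  for (int ch = 0; ch < c; ++ch) {
    const double* xc = px + (size_t)ch * h * w;
    for (int k = 0; k < 9; ++k) {
      int dy = k % 3 - 1;
      int dx = k / 3 - 1;
      double* oc = po + ((size_t)ch * 9 + k) * h * w;
      for (int j = 0; j < w; ++j) {
        int sj = j + dx;
        if (sj < 0 || sj >= w) continue;
        const double* src = xc + (size_t)sj * h;
        double* dst = oc + (size_t)j * h;
        int i0 = std::max(0, -dy), i1 = std::min(h, h - dy);
        for (int i = i0; i < i1; ++i) dst[i] = src[i + dy];
      }
    }
  }
  return out;
}

// Adjoint of im2col3x3: scatter-add columns back into an (h, w, c) array.
// [[Rcpp::export]]
NumericVector col2im3x3_cpp(NumericMatrix cols, int h, int w, int c) {
  NumericVector out((size_t)h * w * c); // zeros
  const double* pc = REAL(cols);
  double* po = REAL(out);
  for (int ch = 0; ch < c; ++ch) {
    double* oc = po + (size_t)ch * h * w;
    for (int k = 0; k < 9; ++k) {
      int dy = k % 3 - 1;
      int dx = k / 3 - 1;
      const double* col = pc + ((size_t)ch * 9 + k) * h * w;
      for (int j = 0; j < w; ++j) {
        int sj = j + dx;
        if (sj < 0 || sj >= w) continue;
        double* dst = oc + (size_t)sj * h;
        const double* src = col + (size_t)j * h;
        int i0 = std::max(0, -dy), i1 = std::min(h, h - dy);
        for (int i = i0; i < i1; ++i) dst[i + dy] += src[i];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(h, w, c);
  return out;
}
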