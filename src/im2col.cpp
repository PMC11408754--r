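#include <Rcpp.h>
using namespace Rcpp;

// Patch-gather for 3x3, stride-1, zero-padded ("same") 2-D convolution.
// x is an H x W x C array in R's column-major layout. The result is a
// (9*C) x (H*W) matrix whose row index is c*9 + t with tap
// t = (dh+1) + 3*(dw+1); this matches the flattening of a weight array
// dim(3, 3, C, Cout) into matrix(9*C, Cout), so a convolution forward pass
// is crossprod(im2col3(x), matrix(W)) plus bias.
// [[Rcpp::export]]
NumericMatrix im2col3(NumericVector x, int H, int W, int C) {
  NumericMatrix out(9 * C, H * W);
  const double* px = x.begin();
  double* po = out.begin();
  const int nrow = 9 * C;
  for (int c = 0; c < C; ++c) {
    const double* plane = px + (size_t)c * H * W;
    for (int t = 0; t < 9; ++t) {
      int dh = t % 3 - 1;
      int dw = t / 3 - 1;
      int row = c * 9 + t;
      int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
      int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
      for (int w = w0; w < w1; ++w) {
        const double* src = plane + (size_t)(w + dw) * H + (h0 + dh);
        double* dst = po + (size_t)(w * H + h0) * nrow + row;
        for (int h = h0; h < h1; ++h) {
          *dst = *src;
          ++src;
          dst += nrow;
        }
      }
    }
  }
  return out;
}
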