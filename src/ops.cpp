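// Production layer kernels for the residual regression network.
//
// Semantics match the pure-R reference operations exactly: true
// (kernel-flipped) convolution, zero padding at the boundary, output
// element (m, n) (1-based) centered on input element (S*m, S*n), output
// spatial size floor(input / stride).  Arrays are column-major R arrays:
// x[h + H*(w + W*c)].

#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static inline int out_size(int n, int S) { return n / S; }

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w,
                           NumericVector b, int S) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2];
  const int K = wd[0], Co = wd[3];
  if (wd[2] != Ci) stop("channel mismatch");
  const int h = (K - 1) / 2;  // small inputs are zero-padded
  const int M = out_size(H, S), N = out_size(W, S);
  NumericVector y(M * N * Co);
  y.attr("dim") = IntegerVector::create(M, N, Co);
  for (int co = 0; co < Co; ++co) {
    for (int ci = 0; ci < Ci; ++ci) {
      const double *xc = &x[(size_t)H * W * ci];
      const double *wc = &w[(size_t)K * K * (ci + (size_t)wd[2] * co)];
      double *yc = &y[(size_t)M * N * co];
      for (int n = 0; n < N; ++n) {
        const int cc = S * (n + 1) - 1;
        for (int m = 0; m < M; ++m) {
          const int cr = S * (m + 1) - 1;
          double acc = 0.0;
          for (int j = -h; j <= h; ++j) {
            const int c = cc + j;
            if (c < 0 || c >= W) continue;
            for (int i = -h; i <= h; ++i) {
              const int r = cr + i;
              if (r < 0 || r >= H) continue;
              // flipped kernel index: (h - i, h - j)
              acc += wc[(h - i) + K * (h - j)] * xc[r + H * c];
            }
          }
          yc[m + M * n] += acc;
        }
      }
    }
    double *yc = &y[(size_t)M * N * co];
    for (int k = 0; k < M * N; ++k) yc[k] += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector g, int S) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = g.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2];
  const int K = wd[0], Co = wd[3];
  const int M = gd[0], N = gd[1];
  const int h = (K - 1) / 2;
  NumericVector gx(x.size()), gw(w.size()), gb(Co);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  for (int co = 0; co < Co; ++co) {
    const double *gc = &g[(size_t)M * N * co];
    double s = 0.0;
    for (int k = 0; k < M * N; ++k) s += gc[k];
    gb[co] = s;
    for (int ci = 0; ci < Ci; ++ci) {
      const double *xc = &x[(size_t)H * W * ci];
      const double *wc = &w[(size_t)K * K * (ci + (size_t)Ci * co)];
      double *gxc = &gx[(size_t)H * W * ci];
      double *gwc = &gw[(size_t)K * K * (ci + (size_t)Ci * co)];
      for (int n = 0; n < N; ++n) {
        const int cc = S * (n + 1) - 1;
        for (int m = 0; m < M; ++m) {
          const int cr = S * (m + 1) - 1;
          const double go = gc[m + M * n];
          if (go == 0.0) continue;
          for (int j = -h; j <= h; ++j) {
            const int c = cc + j;
            if (c < 0 || c >= W) continue;
            for (int i = -h; i <= h; ++i) {
              const int r = cr + i;
              if (r < 0 || r >= H) continue;
              gxc[r + H * c] += wc[(h - i) + K * (h - j)] * go;
              gwc[(h - i) + K * (h - j)] += xc[r + H * c] * go;
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_fwd(NumericVector x, int K, int S) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  if (K > H || K > W) stop("window exceeds input");
  const int h = (K - 1) / 2;
  const int M = out_size(H, S), N = out_size(W, S);
  NumericVector y(M * N * C);
  y.attr("dim") = IntegerVector::create(M, N, C);
  for (int c0 = 0; c0 < C; ++c0) {
    const double *xc = &x[(size_t)H * W * c0];
    double *yc = &y[(size_t)M * N * c0];
    for (int n = 0; n < N; ++n) {
      const int cc = S * (n + 1) - 1;
      for (int m = 0; m < M; ++m) {
        const int cr = S * (m + 1) - 1;
        double best = -DBL_MAX;
        bool trunc = false;
        for (int j = -h; j <= h; ++j) {
          const int c = cc + j;
          if (c < 0 || c >= W) { trunc = true; continue; }
          for (int i = -h; i <= h; ++i) {
            const int r = cr + i;
            if (r < 0 || r >= H) { trunc = true; continue; }
            const double v = xc[r + H * c];
            if (v > best) best = v;
          }
        }
        if (trunc && best < 0.0) best = 0.0;  // zero padding
        yc[m + M * n] = best;
      }
    }
  }
  return y;
}

// Routes the output gradient to each window's argmax (first maximum in
// column-major scan order; padding zeros receive no gradient).
// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector x, NumericVector g, int K, int S) {
  IntegerVector xd = x.attr("dim"), gd = g.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int M = gd[0], N = gd[1];
  const int h = (K - 1) / 2;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  for (int c0 = 0; c0 < C; ++c0) {
    const double *xc = &x[(size_t)H * W * c0];
    const double *gc = &g[(size_t)M * N * c0];
    double *gxc = &gx[(size_t)H * W * c0];
    for (int n = 0; n < N; ++n) {
      const int cc = S * (n + 1) - 1;
      for (int m = 0; m < M; ++m) {
        const int cr = S * (m + 1) - 1;
        double best = -DBL_MAX;
        int arg = -1;
        bool trunc = false;
        for (int j = -h; j <= h; ++j) {
          const int c = cc + j;
          if (c < 0 || c >= W) { trunc = true; continue; }
          for (int i = -h; i <= h; ++i) {
            const int r = cr + i;
            if (r < 0 || r >= H) { trunc = true; continue; }
            const double v = xc[r + H * c];
            if (v > best) { best = v; arg = r + H * c; }
          }
        }
        if (trunc && best < 0.0) arg = -1;  // padding zero won the max
        if (arg >= 0) gxc[arg] += gc[m + M * n];
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_downsample(NumericVector x, int S) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  if (S == 1) return clone(x);
  const int M = out_size(H, S), N = out_size(W, S);
  NumericVector y(M * N * C);
  y.attr("dim") = IntegerVector::create(M, N, C);
  for (int c0 = 0; c0 < C; ++c0) {
    const double *xc = &x[(size_t)H * W * c0];
    double *yc = &y[(size_t)M * N * c0];
    for (int n = 0; n < N; ++n)
      for (int m = 0; m < M; ++m)
        yc[m + M * n] = xc[(S * (m + 1) - 1) + H * (S * (n + 1) - 1)];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_downsample_bwd(NumericVector g, int H, int W, int S) {
  IntegerVector gd = g.attr("dim");
  const int M = gd[0], N = gd[1], C = gd[2];
  NumericVector gx(H * W * C);
  gx.attr("dim") = IntegerVector::create(H, W, C);
  if (S == 1) { std::copy(g.begin(), g.end(), gx.begin()); return gx; }
  for (int c0 = 0; c0 < C; ++c0) {
    const double *gc = &g[(size_t)M * N * c0];
    double *gxc = &gx[(size_t)H * W * c0];
    for (int n = 0; n < N; ++n)
      for (int m = 0; m < M; ++m)
        gxc[(S * (m + 1) - 1) + H * (S * (n + 1) - 1)] += gc[m + M * n];
  }
  return gx;
}
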