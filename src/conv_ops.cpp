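// Convolution kernels for the compact EEG classifier.
//
// Layouts are R column-major arrays:
//   signals      x : (C, T, n)        -- C channels, T samples, n windows
//   temporal out y : (C, T, F, n)     -- F temporal filters
//   depthwise in   : (C, T, F1, n)
//   depthwise out  : (M, T, n), M = F1*F2, map index m = f2 + F2*f1
//
// Temporal convolution is cross-correlation along the time axis with
// "same" zero padding (pad_left = (K-1)/2). Because the time axis has
// stride C, a time shift of s samples is a flat pointer shift of s*C,
// so each (filter, tap) pair is one contiguous saxpy over the window.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_tconv_forward(NumericVector x, NumericMatrix w,
                                int C, int T, int n, int pad_left) {
  const int K = w.nrow(), F = w.ncol();
  const R_xlen_t CT = (R_xlen_t)C * T;
  NumericVector y(CT * F * n);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int i = 0; i < n; ++i) {
    const double* xi = xp + CT * i;
    for (int f = 0; f < F; ++f) {
      double* yi = yp + CT * (f + (R_xlen_t)F * i);
      for (int k = 0; k < K; ++k) {
        const double wv = w(k, f);
        if (wv == 0.0) continue;
        const long sC = (long)(k - pad_left) * C;
        const long j0 = sC < 0 ? -sC : 0;
        const long j1 = CT - 1 - (sC > 0 ? sC : 0);
        const double* xs = xi + sC;
        for (long j = j0; j <= j1; ++j) yi[j] += wv * xs[j];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, T, F, n);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_tconv_backward_x(NumericVector gy, NumericMatrix w,
                                   int C, int T, int n, int pad_left) {
  const int K = w.nrow(), F = w.ncol();
  const R_xlen_t CT = (R_xlen_t)C * T;
  NumericVector gx(CT * n);
  const double* gp = gy.begin();
  double* xp = gx.begin();
  for (int i = 0; i < n; ++i) {
    double* xi = xp + CT * i;
    for (int f = 0; f < F; ++f) {
      const double* gi = gp + CT * (f + (R_xlen_t)F * i);
      for (int k = 0; k < K; ++k) {
        const double wv = w(k, f);
        if (wv == 0.0) continue;
        const long sC = (long)(k - pad_left) * C;
        const long j0 = sC < 0 ? -sC : 0;
        const long j1 = CT - 1 - (sC > 0 ? sC : 0);
        double* xs = xi + sC;
        for (long j = j0; j <= j1; ++j) xs[j] += wv * gi[j];
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(C, T, n);
  return gx;
}

// [[Rcpp::export]]
NumericMatrix cpp_tconv_backward_w(NumericVector x, NumericVector gy,
                                   int C, int T, int n, int F,
                                   int K, int pad_left) {
  const R_xlen_t CT = (R_xlen_t)C * T;
  NumericMatrix gw(K, F);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  for (int i = 0; i < n; ++i) {
    const double* xi = xp + CT * i;
    for (int f = 0; f < F; ++f) {
      const double* gi = gp + CT * (f + (R_xlen_t)F * i);
      for (int k = 0; k < K; ++k) {
        const long sC = (long)(k - pad_left) * C;
        const long j0 = sC < 0 ? -sC : 0;
        const long j1 = CT - 1 - (sC > 0 ? sC : 0);
        const double* xs = xi + sC;
        double acc = 0.0;
        for (long j = j0; j <= j1; ++j) acc += xs[j] * gi[j];
        gw(k, f) += acc;
      }
    }
  }
  return gw;
}

// [[Rcpp::export]]
NumericVector cpp_dwconv_forward(NumericVector x, NumericVector w,
                                 int C, int T, int F1, int F2, int n) {
  const int M = F1 * F2;
  const R_xlen_t CT = (R_xlen_t)C * T;
  NumericVector y((R_xlen_t)M * T * n);
  const double* xp = x.begin();
  const double* wp = w.begin();  // (C, F2, F1)
  double* yp = y.begin();
  for (int i = 0; i < n; ++i) {
    for (int f1 = 0; f1 < F1; ++f1) {
      const double* xi = xp + CT * (f1 + (R_xlen_t)F1 * i);
      for (int f2 = 0; f2 < F2; ++f2) {
        const double* wv = wp + C * (f2 + F2 * f1);
        const int m = f2 + F2 * f1;
        double* yi = yp + (R_xlen_t)M * T * i;
        for (int t = 0; t < T; ++t) {
          const double* xt = xi + (R_xlen_t)C * t;
          double acc = 0.0;
          for (int c = 0; c < C; ++c) acc += wv[c] * xt[c];
          yi[m + (R_xlen_t)M * t] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(M, T, n);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_dwconv_backward_x(NumericVector gy, NumericVector w,
                                    int C, int T, int F1, int F2, int n) {
  const int M = F1 * F2;
  const R_xlen_t CT = (R_xlen_t)C * T;
  NumericVector gx(CT * F1 * n);
  const double* gp = gy.begin();
  const double* wp = w.begin();
  double* xp = gx.begin();
  for (int i = 0; i < n; ++i) {
    for (int f1 = 0; f1 < F1; ++f1) {
      double* xi = xp + CT * (f1 + (R_xlen_t)F1 * i);
      for (int f2 = 0; f2 < F2; ++f2) {
        const double* wv = wp + C * (f2 + F2 * f1);
        const int m = f2 + F2 * f1;
        const double* gi = gp + (R_xlen_t)M * T * i;
        for (int t = 0; t < T; ++t) {
          const double g = gi[m + (R_xlen_t)M * t];
          if (g == 0.0) continue;
          double* xt = xi + (R_xlen_t)C * t;
          for (int c = 0; c < C; ++c) xt[c] += wv[c] * g;
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(C, T, F1, n);
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_dwconv_backward_w(NumericVector x, NumericVector gy,
                                    int C, int T, int F1, int F2, int n) {
  const int M = F1 * F2;
  const R_xlen_t CT = (R_xlen_t)C * T;
  NumericVector gw((R_xlen_t)C * F2 * F1);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* wp = gw.begin();
  for (int i = 0; i < n; ++i) {
    for (int f1 = 0; f1 < F1; ++f1) {
      const double* xi = xp + CT * (f1 + (R_xlen_t)F1 * i);
      for (int f2 = 0; f2 < F2; ++f2) {
        double* wv = wp + C * (f2 + F2 * f1);
        const int m = f2 + F2 * f1;
        const double* gi = gp + (R_xlen_t)M * T * i;
        for (int t = 0; t < T; ++t) {
          const double g = gi[m + (R_xlen_t)M * t];
          if (g == 0.0) continue;
          const double* xt = xi + (R_xlen_t)C * t;
          for (int c = 0; c < C; ++c) wv[c] += xt[c] * g;
        }
      }
    }
  }
  gw.attr("dim") = IntegerVector::create(C, F2, F1);
  return gw;
}
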