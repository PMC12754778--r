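#include <Rcpp.h>
using namespace Rcpp;

// Grayscale erosion/dilation with a non-flat structuring element.
// `se` holds heights; NA marks pixels outside the SE support. Out-of-bounds
// image positions are ignored (no padding), so a constant image opens to
// itself everywhere including corners.
// [[Rcpp::export]]
NumericMatrix cpp_gray_morph(NumericMatrix img, NumericMatrix se, bool erode) {
  int nr = img.nrow(), nc = img.ncol();
  int sr = se.nrow(), sc = se.ncol();
  int cy = sr / 2, cx = sc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best = erode ? R_PosInf : R_NegInf;
      for (int sj = 0; sj < sc; ++sj) {
        int jj = j + sj - cx;
        if (jj < 0 || jj >= nc) continue;
        for (int si = 0; si < sr; ++si) {
          int ii = i + si - cy;
          if (ii < 0 || ii >= nr) continue;
          double h = se(si, sj);
          if (NumericMatrix::is_na(h)) continue;
          double v = erode ? img(ii, jj) - h : img(ii, jj) + h;
          if (erode ? (v < best) : (v > best)) best = v;
        }
      }
      out(i, j) = best;
    }
  }
  return out;
}

// Separable convolution with a symmetric 1-D kernel, replicate boundary.
// Applied along rows (y) then columns (x).
// [[Rcpp::export]]
NumericMatrix cpp_sep_conv(NumericMatrix img, NumericVector kernel) {
  int nr = img.nrow(), nc = img.ncol();
  int kl = kernel.size();
  int kc = kl / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int k = 0; k < kl; ++k) {
        int ii = i + k - kc;
        if (ii < 0) ii = 0;
        if (ii >= nr) ii = nr - 1;
        s += img(ii, j) * kernel[k];
      }
      tmp(i, j) = s;
    }
  }
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int k = 0; k < kl; ++k) {
        int jj = j + k - kc;
        if (jj < 0) jj = 0;
        if (jj >= nc) jj = nc - 1;
        s += tmp(i, jj) * kernel[k];
      }
      out(i, j) = s;
    }
  }
  return out;
}

// 2-D convolution with an arbitrary small kernel, replicate boundary.
// [[Rcpp::export]]
NumericMatrix cpp_conv2(NumericMatrix img, NumericMatrix kernel) {
  int nr = img.nrow(), nc = img.ncol();
  int kr = kernel.nrow(), kc = kernel.ncol();
  int cy = kr / 2, cx = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int sj = 0; sj < kc; ++sj) {
        int jj = j + sj - cx;
        if (jj < 0) jj = 0;
        if (jj >= nc) jj = nc - 1;
        for (int si = 0; si < kr; ++si) {
          int ii = i + si - cy;
          if (ii < 0) ii = 0;
          if (ii >= nr) ii = nr - 1;
          s += img(ii, jj) * kernel(si, sj);
        }
      }
      out(i, j) = s;
    }
  }
  return out;
}

// Strict 8-neighbourhood local maxima above `threshold`. Plateau ties are
// broken deterministically: the pixel must be >= all neighbours and strictly
// greater than neighbours that come later in scan order (larger column, or
// same column and larger row).
// [[Rcpp::export]]
LogicalMatrix cpp_local_max(NumericMatrix img, double threshold) {
  int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = img(i, j);
      if (!(v > threshold)) { out(i, j) = false; continue; }
      bool ok = true;
      for (int dj = -1; dj <= 1 && ok; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          int ii = i + di;
          if (ii < 0 || ii >= nr) continue;
          double w = img(ii, jj);
          bool later = (dj > 0) || (dj == 0 && di > 0);
          if (later ? (w >= v) : (w > v)) { ok = false; break; }
        }
      }
      out(i, j) = ok;
    }
  }
  return out;
}
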