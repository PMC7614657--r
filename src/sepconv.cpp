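#include <Rcpp.h>
using namespace Rcpp;

//' @name sep_conv_cpp
//' @title Separable 2-D convolution with replicate boundary
//' @description Convolves the image columns with `ky`, then rows with `kx`.
//' @param img numeric matrix
//' @param ky,kx odd-length 1-D kernels
//' @return filtered matrix
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix sep_conv_cpp(NumericMatrix img, NumericVector ky,
                           NumericVector kx) {
  const int nr = img.nrow(), nc = img.ncol();
  const int hy = (ky.size() - 1) / 2, hx = (kx.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double *pin = REAL(img), *wky = REAL(ky), *wkx = REAL(kx);
  double *ptmp = REAL(tmp), *pout = REAL(out);
  // columns with ky (replicate ends)
  for (int j = 0; j < nc; ++j) {
    const double *col = pin + (size_t)j * nr;
    double *oc = ptmp + (size_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      if (i >= hy && i < nr - hy) {
        const double *c = col + i - hy;
        for (int t = 0; t < 2 * hy + 1; ++t) s += c[t] * wky[t];
      } else {
        for (int t = -hy; t <= hy; ++t) {
          int ii = i + t;
          if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
          s += col[ii] * wky[t + hy];
        }
      }
      oc[i] = s;
    }
  }
  // rows with kx (replicate ends): accumulate whole columns per tap so the
  // inner loop is contiguous in memory
  for (int j = 0; j < nc; ++j) {
    double *oc = pout + (size_t)j * nr;
    for (int i = 0; i < nr; ++i) oc[i] = 0.0;
    for (int t = -hx; t <= hx; ++t) {
      int jj = j + t;
      if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
      const double *sc = ptmp + (size_t)jj * nr;
      const double w = wkx[t + hx];
      for (int i = 0; i < nr; ++i) oc[i] += w * sc[i];
    }
  }
  return out;
}

//' @name add_blobs_cpp
//' @title Accumulate truncated-Gaussian nuclear blobs into an image
//' @description Adds, in place on a fresh canvas, one isotropic Gaussian
//'   blob per cell, truncated at the nuclear radius (2.5 sigma) and scaled
//'   so each blob's pixel sum equals the cell's total intensity.
//' @param nr,nc image dimensions
//' @param bg uniform background level
//' @param x,y 0-based centroids
//' @param r nuclear radii (px)
//' @param total integrated intensities
//' @return image matrix
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix add_blobs_cpp(int nr, int nc, double bg, NumericVector x,
                            NumericVector y, NumericVector r,
                            NumericVector total) {
  NumericMatrix img(nr, nc);
  double *p = REAL(img);
  std::fill(p, p + (size_t)nr * nc, bg);
  const int n = x.size();
  std::vector<double> w;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i], ri = r[i];
    const double s2 = 2.0 * (ri / 2.5) * (ri / 2.5);
    const int r0 = (int)std::floor(yi - ri), r1 = (int)std::ceil(yi + ri);
    const int c0 = (int)std::floor(xi - ri), c1 = (int)std::ceil(xi + ri);
    const int rr0 = std::max(r0, 0), rr1 = std::min(r1, nr - 1);
    const int cc0 = std::max(c0, 0), cc1 = std::min(c1, nc - 1);
    if (rr0 > rr1 || cc0 > cc1) continue;
    const int wr = rr1 - rr0 + 1, wc = cc1 - cc0 + 1;
    w.assign((size_t)wr * wc, 0.0);
    double sum = 0.0;
    for (int cj = 0; cj < wc; ++cj) {
      const double dx = (cc0 + cj) - xi;
      for (int ri2 = 0; ri2 < wr; ++ri2) {
        const double dy = (rr0 + ri2) - yi;
        const double d2 = dx * dx + dy * dy;
        if (d2 > ri * ri) continue;
        const double g = std::exp(-d2 / s2);
        w[(size_t)cj * wr + ri2] = g;
        sum += g;
      }
    }
    if (sum <= 0.0) continue;
    const double scale = total[i] / sum;
    for (int cj = 0; cj < wc; ++cj) {
      double *col = p + (size_t)(cc0 + cj) * nr + rr0;
      const double *wcol = w.data() + (size_t)cj * wr;
      for (int ri2 = 0; ri2 < wr; ++ri2) col[ri2] += wcol[ri2] * scale;
    }
  }
  return img;
}
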