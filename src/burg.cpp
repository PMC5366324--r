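#include <Rcpp.h>
using namespace Rcpp;

// Burg lattice recursion on a demeaned segment.
// Convention: x_t = sum_k a_k x_{t-k} + e_t, so the prediction-error filter is
// A(z) = 1 - sum_k a_k z^{-k}. Reflection coefficients live in (-1, 1) for a
// stable model; a degenerate (zero-variance) segment yields a = 0, sigma2 = 0.
static void burg_core(const double* x, int n, int p,
                      double* a, double* refl, double* sigma2,
                      double* ef, double* eb, double* atmp) {
  double s0 = 0.0;
  for (int i = 0; i < n; ++i) {
    ef[i] = x[i];
    eb[i] = x[i];
    s0 += x[i] * x[i];
  }
  double sig = s0 / n;
  for (int k = 0; k < p; ++k) { a[k] = 0.0; refl[k] = 0.0; }
  if (sig <= 0.0) { *sigma2 = 0.0; return; }

  // denominator maintained by Andersen's recursion (one dot product saved
  // per order; agrees with the direct sum to ~1e-13 at order 40, n = 256)
  double den = 0.0;
  for (int i = 1; i < n; ++i)
    den += ef[i] * ef[i] + eb[i - 1] * eb[i - 1];

  for (int m = 1; m <= p; ++m) {
    double num = 0.0;
    for (int i = m; i < n; ++i) num += ef[i] * eb[i - 1];
    double kref = (den > 0.0) ? 2.0 * num / den : 0.0;
    refl[m - 1] = kref;
    // order update of prediction coefficients
    for (int j = 0; j < m - 1; ++j) atmp[j] = a[j] - kref * a[m - 2 - j];
    for (int j = 0; j < m - 1; ++j) a[j] = atmp[j];
    a[m - 1] = kref;
    sig *= (1.0 - kref * kref);
    if (sig < 0.0) sig = 0.0;
    // error update (backward in i so eb[i-1] is the previous-order value)
    for (int i = n - 1; i >= m; --i) {
      double f = ef[i], b = eb[i - 1];
      ef[i] = f - kref * b;
      eb[i] = b - kref * f;
    }
    den = den * (1.0 - kref * kref) - ef[m] * ef[m] - eb[n - 1] * eb[n - 1];
    if (den < 0.0) den = 0.0;
  }
  *sigma2 = sig;
}

// [[Rcpp::export(name = ".burg_fit_cpp")]]
List burg_fit_cpp(NumericVector x, int order) {
  int n = x.size();
  if (n <= order)
    stop("segment length (%d) must exceed the AR order (%d)", n, order);
  std::vector<double> xc(n), ef(n), eb(n), atmp(order);
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  for (int i = 0; i < n; ++i) xc[i] = x[i] - mean;
  NumericVector a(order), refl(order);
  double sigma2;
  burg_core(xc.data(), n, order, a.begin(), refl.begin(), &sigma2,
            ef.data(), eb.data(), atmp.data());
  return List::create(_["ar"] = a, _["reflection"] = refl,
                      _["sigma2"] = sigma2, _["mean"] = mean);
}

// Band amplitudes for consecutive sliding windows of one epoch.
// cosmat/sinmat are order x nfreq matrices with entries cos/sin(2*pi*f*k/fs)
// (order-major so each frequency's coefficients are contiguous);
// band_idx (1-based, length nfreq) maps each grid frequency to its band.
// Amplitude at f is sqrt(sigma2 / fs) / |A(f)|; per band the grid mean is
// returned. Output: nwin x nbands.
// [[Rcpp::export(name = ".burg_band_sliding_cpp")]]
NumericMatrix burg_band_sliding_cpp(NumericVector x, int winlen, int step,
                                    int order, double fs,
                                    NumericMatrix cosmat, NumericMatrix sinmat,
                                    IntegerVector band_idx, int nbands) {
  int n = x.size();
  int nfreq = cosmat.ncol();
  if (cosmat.nrow() != order || sinmat.nrow() != order)
    stop("cos/sin grids do not match the AR order");
  int nwin = (n >= winlen) ? (n - winlen) / step + 1 : 0;
  NumericMatrix out(nwin, nbands);
  if (nwin == 0) return out;

  std::vector<double> xc(winlen), ef(winlen), eb(winlen),
      a(order), refl(order), atmp(order);
  std::vector<int> bcount(nbands, 0);
  for (int j = 0; j < nfreq; ++j) bcount[band_idx[j] - 1]++;

  for (int w = 0; w < nwin; ++w) {
    const double* seg = x.begin() + (size_t)w * step;
    double mean = 0.0;
    for (int i = 0; i < winlen; ++i) mean += seg[i];
    mean /= winlen;
    for (int i = 0; i < winlen; ++i) xc[i] = seg[i] - mean;
    double sigma2;
    burg_core(xc.data(), winlen, order, a.data(), refl.data(), &sigma2,
              ef.data(), eb.data(), atmp.data());
    if (sigma2 <= 0.0) continue;  // degenerate window -> zero amplitudes
    double scale = std::sqrt(sigma2 / fs);
    std::vector<double> bsum(nbands, 0.0);
    for (int j = 0; j < nfreq; ++j) {
      double re = 1.0, im = 0.0;
      const double* cr = &cosmat(0, j);  // contiguous column j
      const double* sr = &sinmat(0, j);
      for (int k = 0; k < order; ++k) {
        re -= a[k] * cr[k];
        im += a[k] * sr[k];
      }
      double mod = std::sqrt(re * re + im * im);
      bsum[band_idx[j] - 1] += (mod > 0.0) ? scale / mod : 0.0;
    }
    for (int b = 0; b < nbands; ++b)
      out(w, b) = bcount[b] > 0 ? bsum[b] / bcount[b] : 0.0;
  }
  return out;
}
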