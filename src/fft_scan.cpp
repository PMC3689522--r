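// Hot loop of the one-dimensional FFT direction search: project scattering
// vectors onto many candidate directions, histogram the projections on
// [-smax, smax], FFT each histogram and locate the first significant
// non-origin peak per direction. Kept in C++ because a full hemisphere at
// the default angular step means several thousand FFTs per indexing run.
//
// Peak picking: the projection density itself (a smooth bell over the
// sphere) leaks power into low frequencies, so the raw in-range maximum is
// not a reliable axis signature. Instead, local maxima of the magnitude
// spectrum are scored by their contrast above the neighbouring spectral
// floor, and among near-best peaks the lowest frequency wins — the comb
// fundamental, not a harmonic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// S: n x 3 scattering vectors; T: m x 3 unit projection directions.
// Returns an m x 4 matrix per direction: raw peak magnitude, contrast above
// the local floor, integer peak index, interpolated (sub-bin) peak index.
// [[Rcpp::export]]
NumericMatrix cpp_fft_scan(const arma::mat& S, const arma::mat& T,
                           double smax, int nbins, int m_lo, int m_hi) {
  const int ndir = T.n_rows;
  const int nvec = S.n_rows;
  const int w = 4;                       // half-width for the floor estimate
  if (smax <= 0) stop("smax must be positive");
  if (m_lo < 1) m_lo = 1;
  if (m_hi > nbins / 2 - 1 - w) m_hi = nbins / 2 - 1 - w;
  NumericMatrix out(ndir, 4);
  if (m_hi < m_lo) return out;

  arma::mat P = S * T.t();               // nvec x ndir projections
  arma::vec counts(nbins);
  const double scale = nbins / (2.0 * smax);
  const int lo = std::max(1, m_lo - w);
  const int hi = m_hi + w;
  arma::vec mag(hi + 2);

  for (int d = 0; d < ndir; ++d) {
    counts.zeros();
    for (int j = 0; j < nvec; ++j) {
      int b = (int)std::floor((P(j, d) + smax) * scale);
      if (b < 0) b = 0;
      if (b >= nbins) b = nbins - 1;
      counts(b) += 1.0;
    }
    arma::cx_vec F = arma::fft(counts);
    for (int m = lo - 1; m <= hi + 1 && m < nbins; ++m) mag(m) = std::abs(F(m));

    // local maxima in [m_lo, m_hi], scored by contrast above the floor
    double best_contrast = 0.0;
    int best_m = 0;
    std::vector<int> peaks;
    std::vector<double> contr;
    for (int m = m_lo; m <= m_hi; ++m) {
      if (!(mag(m) > mag(m - 1) && mag(m) >= mag(m + 1))) continue;
      double lmin = mag(m), rmin = mag(m);
      for (int k = std::max(lo, m - w); k < m; ++k) lmin = std::min(lmin, mag(k));
      for (int k = m + 1; k <= std::min(hi, m + w); ++k) rmin = std::min(rmin, mag(k));
      double c = mag(m) - std::max(lmin, rmin);
      peaks.push_back(m);
      contr.push_back(c);
      if (c > best_contrast) { best_contrast = c; best_m = m; }
    }
    if (best_m == 0) continue;
    // first (lowest-frequency) peak among those near the best contrast
    for (size_t i = 0; i < peaks.size(); ++i) {
      if (contr[i] >= 0.8 * best_contrast) { best_m = peaks[i]; best_contrast = contr[i]; break; }
    }
    double y0 = mag(best_m - 1), y1 = mag(best_m), y2 = mag(best_m + 1);
    double denom = y0 - 2.0 * y1 + y2;
    double shift = (std::abs(denom) > 1e-12) ? 0.5 * (y0 - y2) / denom : 0.0;
    if (shift > 0.5) shift = 0.5;
    if (shift < -0.5) shift = -0.5;
    out(d, 0) = y1;
    out(d, 1) = best_contrast;
    out(d, 2) = best_m;
    out(d, 3) = best_m + shift;
  }
  return out;
}
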