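#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Normalized cross-correlation of a feature patch against a same-channel
// band of a cochleagram, evaluated at every valid lag.
//
// At each lag the feature and the cochleagram patch are each mean-subtracted
// and divided by their (population) standard deviations before the inner
// product, giving values in [-1, 1]; a zero-variance cochleagram patch
// yields NCC 0 (silence matches nothing). The feature must have nonzero
// variance (checked in R before calling).
//
// feat: nch x L; band: nch x T (same channel rows), T >= L.
// Returns vector of length T - L + 1.
// [[Rcpp::export]]
NumericVector ncc_trace_cpp(NumericMatrix feat, NumericMatrix band) {
  const int nch = feat.nrow(), L = feat.ncol(), T = band.ncol();
  const int nlag = T - L + 1;
  const double n = (double)(nch * L);
  if (band.nrow() != nch) stop("channel span mismatch");
  if (nlag < 1) stop("cochleagram shorter than feature");
  // z-normalize feature once
  double fs = 0, fss = 0;
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < nch; ++i) { fs += feat(i, j); fss += feat(i, j) * feat(i, j); }
  double fmean = fs / n;
  double fvar = fss / n - fmean * fmean;
  if (fvar <= 0) stop("zero-variance feature");
  double fsd = std::sqrt(fvar);
  std::vector<double> fz(nch * L);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < nch; ++i) fz[j * nch + i] = (feat(i, j) - fmean) / fsd;
  // prefix sums over time of band and band^2 (summed over channels)
  std::vector<double> cs(T + 1, 0.0), css(T + 1, 0.0);
  for (int t = 0; t < T; ++t) {
    double s = 0, ss = 0;
    for (int i = 0; i < nch; ++i) { double v = band(i, t); s += v; ss += v * v; }
    cs[t + 1] = cs[t] + s;
    css[t + 1] = css[t] + ss;
  }
  NumericVector out(nlag);
  const double eps = 1e-12;
  for (int lag = 0; lag < nlag; ++lag) {
    double ps = cs[lag + L] - cs[lag];
    double pss = css[lag + L] - css[lag];
    double pmean = ps / n;
    double pvar = pss / n - pmean * pmean;
    if (pvar <= eps * (1.0 + pss / n)) { out[lag] = 0.0; continue; }
    double cross = 0;
    for (int j = 0; j < L; ++j) {
      const double* fcol = &fz[j * nch];
      for (int i = 0; i < nch; ++i) cross += fcol[i] * band(i, lag + j);
    }
    // sum(fz) = 0, so mean term vanishes
    double v = cross / (n * std::sqrt(pvar));
    if (v > 1.0) v = 1.0; else if (v < -1.0) v = -1.0;
    out[lag] = v;
  }
  return out;
}

// Max NCC (and its lag, 0-based) of one feature against many cochleagram
// bands. maps: list of nch x T_k matrices (already restricted to the
// feature's channels). Maps shorter than the feature get response `short_val`
// (e.g. -1: the feature cannot be detected) when allow_short is true,
// otherwise they raise an error.
// [[Rcpp::export]]
List ncc_max_many_cpp(NumericMatrix feat, List maps, bool allow_short,
                      double short_val) {
  const int K = maps.size();
  NumericVector mx(K);
  IntegerVector at(K);
  for (int k = 0; k < K; ++k) {
    NumericMatrix band = maps[k];
    if (band.ncol() < feat.ncol()) {
      if (!allow_short) stop("cochleagram shorter than feature");
      mx[k] = short_val;
      at[k] = NA_INTEGER;
      continue;
    }
    NumericVector tr = ncc_trace_cpp(feat, band);
    int best = 0;
    for (int i = 1; i < tr.size(); ++i) if (tr[i] > tr[best]) best = i;
    mx[k] = tr[best];
    at[k] = best;
  }
  return List::create(_["max"] = mx, _["lag"] = at);
}
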