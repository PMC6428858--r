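#include <Rcpp.h>
#include <complex>
#include <cmath>
using namespace Rcpp;

// Gammatone-style filterbank cochleagram.
//
// Each channel is a cascade of four identical complex one-pole filters
// (pole radius set by the channel's ERB, pole angle by its CF); the real
// part of the cascade output is the bandpass signal. Per-stage input gain
// (1 - r) makes the gain at CF ~1 for every channel, so relative levels
// across channels are comparable. The bandpass output is half-wave
// rectified, power-law compressed, and averaged within frames.
//
// wave: samples; fs: Hz; cfs: strictly increasing center freqs (Hz);
// frame_rate: frames/s; exponent: compression exponent.
// Returns channels x frames matrix of nonnegative rates.
// [[Rcpp::export]]
NumericMatrix cochleagram_cpp(NumericVector wave, double fs, NumericVector cfs,
                              double frame_rate, double exponent) {
  const int n = wave.size();
  const int nch = cfs.size();
  const int nframes = (int)std::ceil((double)n / fs * frame_rate);
  NumericMatrix out(nch, nframes);
  std::vector<int> frame_of(n);
  std::vector<double> frame_n(nframes, 0.0);
  for (int t = 0; t < n; ++t) {
    int f = (int)std::floor((double)t / fs * frame_rate);
    if (f >= nframes) f = nframes - 1;
    frame_of[t] = f;
    frame_n[f] += 1.0;
  }
  const double twopi = 2.0 * M_PI;
  for (int c = 0; c < nch; ++c) {
    double cf = cfs[c];
    // Glasberg & Moore ERB; 1.019 is the standard gammatone bandwidth factor
    double erb = 24.7 * (4.37 * cf / 1000.0 + 1.0);
    double b = 1.019 * erb;
    double r = std::exp(-twopi * b / fs);
    double w = twopi * cf / fs;
    std::complex<double> a(r * std::cos(w), r * std::sin(w));
    double g = 1.0 - r; // per-stage gain: |H(cf)| ~ 1
    std::complex<double> z1(0, 0), z2(0, 0), z3(0, 0), z4(0, 0);
    for (int t = 0; t < n; ++t) {
      z1 = a * z1 + g * wave[t];
      z2 = a * z2 + g * z1;
      z3 = a * z3 + g * z2;
      z4 = a * z4 + g * z3;
      double y = 2.0 * z4.real(); // bandpass signal
      if (y > 0) {
        out(c, frame_of[t]) += std::pow(y, exponent);
      }
    }
    for (int f = 0; f < nframes; ++f) out(c, f) /= frame_n[f];
  }
  return out;
}
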