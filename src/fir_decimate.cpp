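#include <Rcpp.h>
using namespace Rcpp;

// Symmetric-FIR polyphase decimation: y[, k] = sum_j h[j+m] * x[, k*q + j],
// evaluated only at kept samples, zero-padded at the edges. h must have odd
// length; zero phase follows from symmetry.
// [[Rcpp::export]]
NumericMatrix fir_decimate_cpp(NumericMatrix x, NumericVector h, int q) {
  const int nch = x.nrow(), n = x.ncol(), taps = h.size();
  const int m = (taps - 1) / 2;
  const int nout = (n + q - 1) / q;
  NumericMatrix out(nch, nout);
  for (int k = 0; k < nout; ++k) {
    const int c0 = k * q;
    const int jlo = std::max(-m, -c0), jhi = std::min(m, n - 1 - c0);
    double* op = &out(0, k);
    for (int j = jlo; j <= jhi; ++j) {
      const double hj = h[j + m];
      const double* xp = &x(0, c0 + j);
      for (int ch = 0; ch < nch; ++ch) op[ch] += hj * xp[ch];
    }
  }
  return out;
}
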