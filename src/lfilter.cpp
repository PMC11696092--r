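#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter pass over a raw buffer.
static void df2t_pass(const std::vector<double>& b,
                      const std::vector<double>& a,
                      const std::vector<double>& zi_unit,
                      double* x, int m) {
  int n = (int) b.size();
  std::vector<double> z(n - 1);
  for (int k = 0; k < n - 1; ++k) z[k] = zi_unit[k] * x[0];
  for (int i = 0; i < m; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int k = 0; k < n - 2; ++k) {
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    }
    z[n - 2] = b[n - 1] * xi - a[n - 1] * yi;
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) IIR filtering of every column of X,
// with odd-reflection padding of length `pad` and steady-state initial
// conditions `zi` (state for unit input; scaled by the first sample of
// each pass). Returns a matrix of the same shape as X.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt_mat(NumericVector b, NumericVector a,
                               NumericMatrix X, int pad,
                               NumericVector zi) {
  int m = X.nrow(), nc = X.ncol();
  if (m <= pad + 1) stop("signal too short for the requested padding");
  std::vector<double> bv(b.begin(), b.end());
  std::vector<double> av(a.begin(), a.end());
  std::vector<double> ziv(zi.begin(), zi.end());
  NumericMatrix out(m, nc);
  int mt = m + 2 * pad;
  std::vector<double> buf(mt);
  for (int c = 0; c < nc; ++c) {
    const double* x = &X(0, c);
    for (int i = 0; i < pad; ++i) buf[i] = 2.0 * x[0] - x[pad - i];
    for (int i = 0; i < m; ++i) buf[pad + i] = x[i];
    for (int i = 0; i < pad; ++i) buf[pad + m + i] = 2.0 * x[m - 1] - x[m - 2 - i];
    df2t_pass(bv, av, ziv, buf.data(), mt);
    std::reverse(buf.begin(), buf.end());
    df2t_pass(bv, av, ziv, buf.data(), mt);
    std::reverse(buf.begin(), buf.end());
    for (int i = 0; i < m; ++i) out(i, c) = buf[pad + i];
  }
  return out;
}
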