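#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filtering. Coefficients must be normalized
// so a[0] == 1 (signal::butter output already is). The order-6 and order-3
// state loops are unrolled because they run over tens of millions of
// samples per recording.

template <int NZ>
static inline void df2t_pass(const double* b, const double* a,
                             const double* x, double* y, int n,
                             const double* zi) {
  double z[NZ];
  for (int k = 0; k < NZ; ++k) z[k] = zi[k] * x[0];
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int k = 0; k < NZ - 1; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    z[NZ - 1] = b[NZ] * xi - a[NZ] * yi;
    y[i] = yi;
  }
}

template <int NZ>
static inline void df2t_pass_rev(const double* b, const double* a,
                                 double* y, int n, const double* zi) {
  double z[NZ];
  for (int k = 0; k < NZ; ++k) z[k] = zi[k] * y[n - 1];
  for (int i = n - 1; i >= 0; --i) {
    const double xi = y[i];
    const double yi = b[0] * xi + z[0];
    for (int k = 0; k < NZ - 1; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    z[NZ - 1] = b[NZ] * xi - a[NZ] * yi;
    y[i] = yi;
  }
}

static void df2t_generic(const std::vector<double>& b,
                         const std::vector<double>& a,
                         const double* x, double* y, int n, int nz,
                         const double* zi) {
  std::vector<double> z(nz);
  for (int k = 0; k < nz; ++k) z[k] = zi[k] * x[0];
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int k = 0; k < nz - 1; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    z[nz - 1] = b[nz] * xi - a[nz] * yi;
    y[i] = yi;
  }
}

static void pad_coeffs(NumericVector b, NumericVector a, int nz,
                       std::vector<double>& bb, std::vector<double>& aa) {
  bb.assign(nz + 1, 0.0);
  aa.assign(nz + 1, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
}

// single forward pass; zi is the steady-state unit-step state, scaled by
// the first sample inside (pass zeros for a cold start)
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  const int n = x.size();
  const int nz = std::max(b.size(), a.size()) - 1;
  std::vector<double> bb, aa;
  pad_coeffs(b, a, nz, bb, aa);
  NumericVector y(n);
  if (nz == 6) df2t_pass<6>(bb.data(), aa.data(), x.begin(), y.begin(), n,
                            zi.begin());
  else if (nz == 3) df2t_pass<3>(bb.data(), aa.data(), x.begin(), y.begin(),
                                 n, zi.begin());
  else df2t_generic(bb, aa, x.begin(), y.begin(), n, nz, zi.begin());
  return y;
}

// forward then backward pass (zero phase), both passes initialized at their
// steady state for the respective first sample; padding is the caller's job
// [[Rcpp::export]]
NumericVector iir_filtfilt_cpp(NumericVector b, NumericVector a,
                               NumericVector x, NumericVector zi) {
  const int n = x.size();
  const int nz = std::max(b.size(), a.size()) - 1;
  std::vector<double> bb, aa;
  pad_coeffs(b, a, nz, bb, aa);
  NumericVector y(n);
  if (nz == 6) {
    df2t_pass<6>(bb.data(), aa.data(), x.begin(), y.begin(), n, zi.begin());
    df2t_pass_rev<6>(bb.data(), aa.data(), y.begin(), n, zi.begin());
  } else if (nz == 3) {
    df2t_pass<3>(bb.data(), aa.data(), x.begin(), y.begin(), n, zi.begin());
    df2t_pass_rev<3>(bb.data(), aa.data(), y.begin(), n, zi.begin());
  } else {
    df2t_generic(bb, aa, x.begin(), y.begin(), n, nz, zi.begin());
    std::reverse(y.begin(), y.end());
    NumericVector y2(n);
    df2t_generic(bb, aa, y.begin(), y2.begin(), n, nz, zi.begin());
    std::reverse(y2.begin(), y2.end());
    return y2;
  }
  return y;
}
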