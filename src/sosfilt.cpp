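#include <Rcpp.h>
using namespace Rcpp;

// Forward-pass filtering of each column of x through a cascade of biquad
// sections (direct form II transposed, zero initial conditions).
// sos: list of lists with elements b (length 3) and a (length 3, a[0]=1).
// [[Rcpp::export]]
NumericMatrix sosfilt_cpp(List sos, NumericMatrix x) {
  int n = x.nrow(), m = x.ncol(), ns = sos.size();
  NumericMatrix y = clone(x);
  std::vector<double> b0(ns), b1(ns), b2(ns), a1(ns), a2(ns);
  for (int s = 0; s < ns; ++s) {
    List sec = sos[s];
    NumericVector b = sec["b"], a = sec["a"];
    b0[s] = b[0]; b1[s] = b[1]; b2[s] = b[2];
    a1[s] = a[1]; a2[s] = a[2];
  }
  for (int j = 0; j < m; ++j) {
    for (int s = 0; s < ns; ++s) {
      double z1 = 0.0, z2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double xi = y(i, j);
        double yi = b0[s] * xi + z1;
        z1 = b1[s] * xi - a1[s] * yi + z2;
        z2 = b2[s] * xi - a2[s] * yi;
        y(i, j) = yi;
      }
    }
  }
  return y;
}
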