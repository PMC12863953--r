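#include <Rcpp.h>
using namespace Rcpp;

// Numerator relationship matrix by the tabular (recursive) method.
// sire/dam are 1-based indices into the pedigree order, 0 = unknown.
// Requires parents to precede offspring; validated on the R side.
// [[Rcpp::export(name = ".tabular_A")]]
NumericMatrix tabular_A(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1;
    for (int j = 0; j < i; ++j) {
      double aij = 0.0;
      if (s >= 0) aij += 0.5 * A(j, s);
      if (d >= 0) aij += 0.5 * A(j, d);
      A(i, j) = A(j, i) = aij;
    }
    double f = 0.0;                      // F_i = 0.5 * a(sire, dam)
    if (s >= 0 && d >= 0) f = 0.5 * A(s, d);
    A(i, i) = 1.0 + f;
  }
  return A;
}

// Diagonal-only variant (inbreeding coefficients) kept with the full
// routine: it is the same recursion, but we still need the full upper
// triangle to reach a(s, d), so there is no cheaper exact shortcut here.
// [[Rcpp::export(name = ".inbreeding_from_pedigree")]]
NumericVector inbreeding_from_pedigree(IntegerVector sire, IntegerVector dam) {
  NumericMatrix A = tabular_A(sire, dam);
  const int n = sire.size();
  NumericVector f(n);
  for (int i = 0; i < n; ++i) f[i] = A(i, i) - 1.0;
  return f;
}
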