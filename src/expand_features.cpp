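// Fast feature expansion: fills the derived-feature design matrix from the
// scaled variable matrix in one pass, avoiding large temporaries.
//
// class codes: 1 = linear, 2 = quadratic, 3 = product, 4 = threshold,
// 5 = forward hinge, 6 = reverse hinge.  var1/var2 are 1-based column
// indices into z; knot is the scaled knot position.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix expand_features_cpp(const NumericMatrix& z,
                                  const IntegerVector& cls,
                                  const IntegerVector& var1,
                                  const IntegerVector& var2,
                                  const NumericVector& knot) {
  const int n = z.nrow();
  const int p = cls.size();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    const double* x = &z(0, var1[j] - 1);
    double* o = &out(0, j);
    switch (cls[j]) {
    case 1:
      std::copy(x, x + n, o);
      break;
    case 2:
      for (int i = 0; i < n; ++i) o[i] = x[i] * x[i];
      break;
    case 3: {
      const double* y = &z(0, var2[j] - 1);
      for (int i = 0; i < n; ++i) o[i] = x[i] * y[i];
      break;
    }
    case 4: {
      const double k = knot[j];
      for (int i = 0; i < n; ++i) o[i] = x[i] > k ? 1.0 : 0.0;
      break;
    }
    case 5: {
      const double k = knot[j], s = 1.0 / (1.0 - knot[j]);
      for (int i = 0; i < n; ++i) o[i] = x[i] > k ? (x[i] - k) * s : 0.0;
      break;
    }
    case 6: {
      const double k = knot[j], s = 1.0 / knot[j];
      for (int i = 0; i < n; ++i) o[i] = x[i] < k ? (k - x[i]) * s : 0.0;
      break;
    }
    default:
      stop("unknown feature class code");
    }
  }
  return out;
}
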