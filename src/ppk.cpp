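#include <Rcpp.h>
using namespace Rcpp;

// Probability product kernel Gram matrix over peak lists.
// Peaks must be sorted ascending by m/z and intensities normalized to sum 1
// (done on the R side). Pairs further apart than cutoff*sigma contribute
// less than exp(-cutoff^2/4) relatively and are skipped via a sliding
// window over the sorted mass axis; cutoff = 12 keeps the truncation at
// machine precision.
// [[Rcpp::export]]
NumericMatrix ppk_gram_cpp(List mz_rows, List w_rows, List mz_cols,
                           List w_cols, double sigma, bool symmetric,
                           double cutoff) {
  const int nr = mz_rows.size(), nc = mz_cols.size();
  const double norm = 1.0 / std::sqrt(4.0 * M_PI * sigma * sigma);
  const double inv = 1.0 / (4.0 * sigma * sigma);
  const double window = cutoff * sigma;
  NumericMatrix K(nr, nc);
  for (int i = 0; i < nr; ++i) {
    const NumericVector ma = mz_rows[i], wa = w_rows[i];
    const int na = ma.size();
    const int jstart = symmetric ? i : 0;
    for (int j = jstart; j < nc; ++j) {
      const NumericVector mb = mz_cols[j], wb = w_cols[j];
      const int nb = mb.size();
      double acc = 0.0;
      int lo = 0;
      for (int a = 0; a < na; ++a) {
        const double m = ma[a];
        while (lo < nb && mb[lo] < m - window) ++lo;
        for (int b = lo; b < nb && mb[b] <= m + window; ++b) {
          const double d = m - mb[b];
          acc += wa[a] * wb[b] * std::exp(-d * d * inv);
        }
      }
      K(i, j) = acc * norm;
      if (symmetric) K(j, i) = K(i, j);
    }
  }
  return K;
}
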