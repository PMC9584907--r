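#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sliding log-odds scores of a PWM over integer-encoded sequences.
// seqs: list of IntegerVector with codes 0..3 (A,C,G,T); negative = ambiguous.
// lo: L x 4 matrix of per-position log-odds. Returns, per sequence, the
// score at every offset (NA where the window covers an ambiguous base).
// Scores are accumulated left-to-right so they are bit-identical to a
// naive per-window sum in the same order.
// [[Rcpp::export]]
List cpp_scan(List seqs, NumericMatrix lo) {
  const int L = lo.nrow();
  const int n = seqs.size();
  // row-major copy: w[j*4 + base]
  std::vector<double> w(static_cast<size_t>(L) * 4);
  for (int j = 0; j < L; ++j)
    for (int b = 0; b < 4; ++b) w[j * 4 + b] = lo(j, b);
  List out(n);
  for (int s = 0; s < n; ++s) {
    IntegerVector seq = seqs[s];
    const int* sp = INTEGER(seq);
    const int len = seq.size();
    const int noff = len - L + 1;
    if (noff <= 0) { out[s] = NumericVector(0); continue; }
    NumericVector sc(noff);
    double* scp = REAL(sc);
    for (int o = 0; o < noff; ++o) {
      double acc = 0.0;
      bool ok = true;
      const int* base = sp + o;
      for (int j = 0; j < L; ++j) {
        const int b = base[j];
        if (static_cast<unsigned>(b) > 3u) { ok = false; break; }
        acc += w[j * 4 + b];
      }
      scp[o] = ok ? acc : NA_REAL;
    }
    out[s] = sc;
  }
  return out;
}
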