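#include <Rcpp.h>
using namespace Rcpp;

// Nearest-taxon minimum distances: M(k, j) = min over taxa l present in
// sample j of D(k, l). D is the full taxon x taxon patristic matrix and
// members lists the (1-based) row indices of the taxa present in each
// sample. betaMNTD for all sample pairs then follows from one matrix
// product in R, so null replicates only pay for this kernel.
// [[Rcpp::export]]
NumericMatrix nearest_taxon_min(NumericMatrix D, List members) {
  int T = D.nrow(), S = members.size();
  NumericMatrix M(T, S);
  for (int j = 0; j < S; ++j) {
    IntegerVector idx = members[j];
    int t = idx.size();
    for (int k = 0; k < T; ++k) {
      double best = R_PosInf;
      for (int a = 0; a < t; ++a) {
        double d = D(k, idx[a] - 1);
        if (d < best) best = d;
      }
      M(k, j) = best;
    }
  }
  return M;
}
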