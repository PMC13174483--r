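#include <Rcpp.h>
using namespace Rcpp;

// Mass-action derivative for a compiled reaction network.
//
// r1, r2: 0-based indices of the first/second reactant of each reaction
//         (r2 = -1 for unimolecular reactions).
// si, sj, sv: triplet form of the net stoichiometry matrix (species index,
//         reaction index, net coefficient), 0-based.
// Called once per solver step, so it avoids any allocation beyond the
// output vector.

// [[Rcpp::export]]
NumericVector massActionDeriv(NumericVector y, NumericVector k,
                              IntegerVector r1, IntegerVector r2,
                              IntegerVector si, IntegerVector sj,
                              NumericVector sv) {
  const int nr = k.size();
  const int nnz = si.size();
  NumericVector dy(y.size());
  std::vector<double> v(nr);
  for (int j = 0; j < nr; ++j) {
    double rate = k[j] * y[r1[j]];
    if (r2[j] >= 0) rate *= y[r2[j]];
    v[j] = rate;
  }
  for (int t = 0; t < nnz; ++t) {
    dy[si[t]] += sv[t] * v[sj[t]];
  }
  return dy;
}

// [[Rcpp::export]]
NumericVector massActionRates(NumericVector y, NumericVector k,
                              IntegerVector r1, IntegerVector r2) {
  const int nr = k.size();
  NumericVector v(nr);
  for (int j = 0; j < nr; ++j) {
    double rate = k[j] * y[r1[j]];
    if (r2[j] >= 0) rate *= y[r2[j]];
    v[j] = rate;
  }
  return v;
}
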