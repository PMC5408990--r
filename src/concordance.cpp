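// Harrell's c kernel: weighted comparable / concordant pair counts for
// censored ages at diagnosis with delayed entry. Plain O(events * n) loop;
// no allocations, so it scales to full cohorts and bootstrap replication.

#include <Rcpp.h>

// [[Rcpp::export]]
Rcpp::List cindex_cpp(Rcpp::NumericVector entry, Rcpp::NumericVector stop,
                      Rcpp::IntegerVector status, Rcpp::NumericVector score,
                      Rcpp::NumericVector w) {
  int n = stop.size();
  double conc = 0.0, pairs = 0.0;
  long long npairs = 0;
  for (int i = 0; i < n; ++i) {
    if (status[i] != 1) continue;
    double ti = stop[i], si = score[i], wi = w[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (stop[j] > ti && entry[j] < ti) {
        double ww = wi * w[j];
        pairs += ww;
        ++npairs;
        if (si > score[j]) conc += ww;
        else if (si == score[j]) conc += 0.5 * ww;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("conc") = conc,
                            Rcpp::Named("pairs") = pairs,
                            Rcpp::Named("n_pairs") = (double)npairs);
}
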