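#include <Rcpp.h>
using namespace Rcpp;

// Sequential RW/softmax likelihood recursion. Values start at 0, only the
// chosen cue updates, and each trial contributes -log P(chosen | values,
// beta) under a numerically stabilized softmax. Indices are 1-based (from
// R's match()).
// [[Rcpp::export(name = ".rw_nll_core_cpp")]]
List rw_nll_core_cpp(NumericVector alpha_by_cue, double beta, List avail_idx,
                     IntegerVector chosen_idx, IntegerVector within_idx,
                     NumericVector outcome, int n_cues, bool return_pe) {
  int n = outcome.size();
  std::vector<double> v(n_cues, 0.0);
  double nll = 0.0;
  NumericVector pe = return_pe ? NumericVector(n) : NumericVector(0);
  NumericVector val_chosen = return_pe ? NumericVector(n) : NumericVector(0);
  for (int i = 0; i < n; ++i) {
    IntegerVector ai = avail_idx[i];
    int k = ai.size();
    double m = R_NegInf;
    for (int j = 0; j < k; ++j) {
      double b = beta * v[ai[j] - 1];
      if (b > m) m = b;
    }
    double denom = 0.0;
    for (int j = 0; j < k; ++j) {
      denom += std::exp(beta * v[ai[j] - 1] - m);
    }
    double b_ch = beta * v[ai[within_idx[i] - 1] - 1];
    nll += std::log(denom) - (b_ch - m);
    int ci = chosen_idx[i] - 1;
    double e = outcome[i] - v[ci];
    if (return_pe) {
      pe[i] = e;
      val_chosen[i] = v[ci];
    }
    v[ci] += alpha_by_cue[ci] * e;
  }
  if (return_pe) {
    return List::create(_["nll"] = nll, _["pe"] = pe,
                        _["value_chosen"] = val_chosen);
  }
  return List::create(_["nll"] = nll);
}
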