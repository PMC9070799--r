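#include <Rcpp.h>
using namespace Rcpp;

// Per-elongation-step TWnTE efficiencies. Species not translated at a step
// only relax geometrically toward their global supply, so their state is
// updated lazily when next translated: after g idle steps,
// S <- S0 + (1 - beta)^g (S - S0).
// [[Rcpp::export(name = ".twnte_steps_cpp")]]
NumericVector twnte_steps_cpp(IntegerVector idx, NumericVector S0,
                              NumericVector D, NumericVector alpha_i,
                              double beta) {
  const int L = idx.size();
  const int K = S0.size();
  NumericVector eff(L);
  std::vector<double> S(S0.begin(), S0.end());
  std::vector<int> last(K, 0);
  const double one_b = 1.0 - beta;
  for (int t = 1; t <= L; ++t) {
    const int c = idx[t - 1] - 1;
    const int gap = t - 1 - last[c];
    if (gap > 0)
      S[c] = S0[c] + std::pow(one_b, gap) * (S[c] - S0[c]);
    eff[t - 1] = S[c] / D[c];
    S[c] = beta * S0[c] + one_b * (1.0 - alpha_i[c]) * S[c];
    if (S[c] < 0.0) S[c] = 0.0;
    last[c] = t;
  }
  return eff;
}
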