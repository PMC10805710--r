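#include <Rcpp.h>
using namespace Rcpp;

// Optimal penalised least-squares changepoint detection (PELT).
// Points are ordered by genomic position; each point belongs to one of
// `ntrack` subtracks and the segment cost is the sum over subtracks of the
// within-segment sum of squared deviations from the subtrack mean, so the
// subtracks share breakpoints (joint segmentation).
//
// Returns 1-based indices of the last point of each segment.

// [[Rcpp::export]]
IntegerVector pelt_segment(NumericVector y, IntegerVector track, int ntrack,
                           double penalty, int minseg) {
  const int n = y.size();
  if (n == 0) return IntegerVector(0);
  if (minseg < 1) minseg = 1;

  // prefix sums per track at every combined index
  std::vector<std::vector<double> > s1(ntrack, std::vector<double>(n + 1, 0.0));
  std::vector<std::vector<double> > s2(ntrack, std::vector<double>(n + 1, 0.0));
  std::vector<std::vector<int> >    cn(ntrack, std::vector<int>(n + 1, 0));
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < ntrack; ++t) {
      s1[t][i + 1] = s1[t][i];
      s2[t][i + 1] = s2[t][i];
      cn[t][i + 1] = cn[t][i];
    }
    int t = track[i];
    s1[t][i + 1] += y[i];
    s2[t][i + 1] += y[i] * y[i];
    cn[t][i + 1] += 1;
  }

  // cost of segment (a, b] (points a+1..b)
  auto segcost = [&](int a, int b) {
    double c = 0.0;
    for (int t = 0; t < ntrack; ++t) {
      int m = cn[t][b] - cn[t][a];
      if (m > 0) {
        double sm = s1[t][b] - s1[t][a];
        c += (s2[t][b] - s2[t][a]) - sm * sm / m;
      }
    }
    return c;
  };

  std::vector<double> F(n + 1, R_PosInf);
  std::vector<int> prev(n + 1, 0);
  F[0] = -penalty;
  std::vector<int> cand;
  cand.push_back(0);

  for (int tau = minseg; tau <= n; ++tau) {
    double best = R_PosInf;
    int arg = 0;
    std::vector<double> partial(cand.size());
    for (size_t k = 0; k < cand.size(); ++k) {
      int s = cand[k];
      if (tau - s < minseg) { partial[k] = R_PosInf; continue; }
      double v = F[s] + segcost(s, tau);
      partial[k] = v;
      if (v + penalty < best) { best = v + penalty; arg = s; }
    }
    F[tau] = best;
    prev[tau] = arg;
    // prune (K = 0 for SSE cost)
    std::vector<int> keep;
    for (size_t k = 0; k < cand.size(); ++k) {
      if (partial[k] == R_PosInf) { keep.push_back(cand[k]); continue; }
      if (partial[k] <= F[tau]) keep.push_back(cand[k]);
    }
    keep.push_back(tau);
    cand = keep;
  }

  // backtrack
  std::vector<int> ends;
  int tau = n;
  while (tau > 0) {
    ends.push_back(tau);
    tau = prev[tau];
  }
  std::reverse(ends.begin(), ends.end());
  return wrap(ends);
}
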