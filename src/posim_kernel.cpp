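#include <Rcpp.h>
using namespace Rcpp;

// Positional similarity scores of a query q against a training sequence k.
//
// Sequences arrive as 0-based integer codes into the similarity matrix
// `sim`.  For fragment length F, every ungapped window pair
//   (q[i..i+F-1], k[i+h..i+h+F-1])
// fully inside both sequences is scored as the sum of residue similarities;
// position p receives the maximum rate over all windows covering p at all
// shifts h.  Positions covered by no admissible window score 0.
//
// One pass per diagonal (fixed h): window rates by a running sum, then a
// per-position maximum over the F windows covering each position with a
// monotonic deque, giving O(len(q) * len(k)) per pair overall.
// [[Rcpp::export]]
NumericVector posim_kernel(const IntegerVector& q, const IntegerVector& k,
                           const NumericMatrix& sim, const int F) {
  const int m = q.size(), n = k.size();
  if (F < 1) stop("fragment length must be >= 1");
  NumericVector S(m, R_NegInf);
  if (m >= F && n >= F) {
    std::vector<double> rate;
    std::vector<int> dq;  // indices of candidate windows, rates decreasing
    for (int h = 1 - m; h <= n - 1; ++h) {
      // query index j (0-based) is matched with k index j + h
      const int jlo = std::max(0, -h);
      const int jhi = std::min(m - 1, n - 1 - h);
      const int L = jhi - jlo + 1;
      if (L < F) continue;
      const int nwin = L - F + 1;  // windows start at j = jlo + t, t in [0, nwin)
      rate.assign(nwin, 0.0);
      double s = 0.0;
      for (int t = 0; t < F; ++t) s += sim(q[jlo + t], k[jlo + t + h]);
      rate[0] = s;
      for (int t = 1; t < nwin; ++t) {
        s += sim(q[jlo + t + F - 1], k[jlo + t + F - 1 + h]) -
             sim(q[jlo + t - 1], k[jlo + t - 1 + h]);
        rate[t] = s;
      }
      // position p = jlo + prel is covered by windows t in
      // [prel - F + 1, prel] intersected with [0, nwin - 1]
      dq.clear();
      size_t head = 0;
      for (int prel = 0; prel < L; ++prel) {
        if (prel < nwin) {
          while (dq.size() > head && rate[dq.back()] <= rate[prel])
            dq.pop_back();
          dq.push_back(prel);
        }
        while (head < dq.size() && dq[head] < prel - F + 1) ++head;
        if (head < dq.size()) {
          const double val = rate[dq[head]];
          if (val > S[jlo + prel]) S[jlo + prel] = val;
        }
      }
    }
  }
  for (int p = 0; p < m; ++p)
    if (S[p] == R_NegInf) S[p] = 0.0;
  return S;
}
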