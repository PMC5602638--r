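#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Sliding-window maximum over the bins k1..k2 positions to the LEFT of each
// bin, via a monotonic deque (amortized O(n)). Windows are truncated at the
// track boundary; a window with no in-range bin yields -Inf (the caller
// treats such points as not callable). Right-side maxima are obtained by
// running this on the reversed vector.
// [[Rcpp::export]]
NumericVector window_max_left(NumericVector x, int k1, int k2) {
  int n = x.size();
  if (k1 < 1 || k2 < k1) stop("window offsets must satisfy 1 <= k1 <= k2");
  NumericVector out(n, R_NegInf);
  std::deque<int> dq;  // indices with decreasing values
  for (int i = 0; i < n; ++i) {
    int hi = i - k1;   // newest index entering the window
    int lo = i - k2;   // oldest index still in the window
    if (hi >= 0) {
      while (!dq.empty() && x[dq.back()] <= x[hi]) dq.pop_back();
      dq.push_back(hi);
    }
    while (!dq.empty() && dq.front() < lo) dq.pop_front();
    if (!dq.empty()) out[i] = x[dq.front()];
  }
  return out;
}
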