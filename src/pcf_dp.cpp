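#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact penalized least-squares piecewise-constant fit of one ordered series.
//
// Minimises  sum_segments SSE(segment) + gamma * (n_segments - 1)
// subject to every segment containing >= min_probes probes (the caller
// handles series shorter than min_probes).  O(n^2) dynamic program over the
// last breakpoint with prefix sums; ties broken toward fewer segments, then
// toward the earlier segment start.
//
// Returns integer vector of 1-based segment start indices.
// [[Rcpp::export(name = ".pcf_dp")]]
IntegerVector pcf_dp(NumericVector y, double gamma, int min_probes) {
  const int n = y.size();
  if (n < 1) stop("empty series");
  if (min_probes < 1) stop("min_probes must be >= 1");

  std::vector<long double> s1(n + 1, 0.0L), s2(n + 1, 0.0L);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + (long double)y[i];
    s2[i + 1] = s2[i] + (long double)y[i] * (long double)y[i];
  }

  // cost[j]: optimal cost of y[0..j-1]; nseg[j]: its segment count;
  // prev[j]: start index (1-based) of the last segment in the optimum.
  std::vector<long double> cost(n + 1, 0.0L);
  std::vector<int> nseg(n + 1, 0), prev(n + 1, 0);
  cost[0] = -gamma;  // first segment carries no penalty

  for (int j = 1; j <= n; ++j) {
    bool found = false;
    long double best = 0.0L;
    int bestk = 0, besti = 0;
    // last segment spans i..j (1-based), length j - i + 1 >= min_probes
    for (int i = 1; i + min_probes - 1 <= j; ++i) {
      int ilen = j - i + 1;
      // all earlier probes must themselves be segmentable
      if (i - 1 != 0 && i - 1 < min_probes) continue;
      long double sum = s1[j] - s1[i - 1];
      long double sse = (s2[j] - s2[i - 1]) - sum * sum / (long double)ilen;
      long double c = cost[i - 1] + sse + gamma;
      int k = nseg[i - 1] + 1;
      long double eps = 1e-10L * (std::fabs((double)c) + 1.0L);
      if (!found || c < best - eps ||
          (c <= best + eps && k < bestk)) {
        // ascending i: first hit among cost+count ties keeps the
        // earlier breakpoint
        found = true; best = c; bestk = k; besti = i;
      }
    }
    if (!found) {  // j < min_probes: unreachable except via whole prefix
      best = (s2[j] - s1[j] * s1[j] / (long double)j);
      bestk = 1; besti = 1;
    }
    cost[j] = best; nseg[j] = bestk; prev[j] = besti;
  }

  std::vector<int> starts;
  int j = n;
  while (j > 0) {
    starts.push_back(prev[j]);
    j = prev[j] - 1;
  }
  std::reverse(starts.begin(), starts.end());
  return wrap(starts);
}
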