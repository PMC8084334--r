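// Greedy CART split search. Incremental Gini / variance updates make the
// cost O(n log n) per candidate feature, independent of the class count.
#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
List best_split_cpp(NumericMatrix X, IntegerVector idx, IntegerVector feats,
                    NumericVector y, int K) {
  const int n = idx.size();
  double best_score = R_PosInf, best_thr = 0;
  int best_feat = -1;
  std::vector<int> ord(n);
  std::vector<double> xv(n), yv(n);
  std::vector<double> cntL, cntR;
  for (int fi = 0; fi < feats.size(); ++fi) {
    const int f = feats[fi] - 1;
    for (int i = 0; i < n; ++i) xv[i] = X(idx[i] - 1, f);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return xv[a] < xv[b]; });
    if (K > 0) {
      // classification: Gini via running sums of squared class counts
      cntL.assign(K, 0.0); cntR.assign(K, 0.0);
      for (int i = 0; i < n; ++i) cntR[(int)y[ord[i]] - 1] += 1.0;
      double SL = 0, SR = 0;
      for (int k = 0; k < K; ++k) SR += cntR[k] * cntR[k];
      for (int i = 0; i < n - 1; ++i) {
        const int c = (int)y[ord[i]] - 1;
        SL += 2.0 * cntL[c] + 1.0; cntL[c] += 1.0;
        SR -= 2.0 * cntR[c] - 1.0; cntR[c] -= 1.0;
        const double xl = xv[ord[i]], xr = xv[ord[i + 1]];
        if (xl >= xr) continue;
        const double nl = i + 1.0, nr = n - i - 1.0;
        const double score = (nl * (1.0 - SL / (nl * nl)) +
                              nr * (1.0 - SR / (nr * nr))) / n;
        if (score < best_score) {
          best_score = score; best_feat = f + 1; best_thr = (xl + xr) / 2.0;
        }
      }
    } else {
      // regression: total SSE of the two children
      for (int i = 0; i < n; ++i) yv[i] = y[ord[i]];
      double ts = 0, ts2 = 0;
      for (int i = 0; i < n; ++i) { ts += yv[i]; ts2 += yv[i] * yv[i]; }
      double cs = 0, cs2 = 0;
      for (int i = 0; i < n - 1; ++i) {
        cs += yv[i]; cs2 += yv[i] * yv[i];
        const double xl = xv[ord[i]], xr = xv[ord[i + 1]];
        if (xl >= xr) continue;
        const double nl = i + 1.0, nr = n - i - 1.0;
        const double sse = (cs2 - cs * cs / nl) +
                           ((ts2 - cs2) - (ts - cs) * (ts - cs) / nr);
        if (sse < best_score) {
          best_score = sse; best_feat = f + 1; best_thr = (xl + xr) / 2.0;
        }
      }
    }
  }
  return List::create(_["feature"] = best_feat, _["threshold"] = best_thr,
                      _["score"] = best_score);
}
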