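#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// All-pairs shortest paths by Dijkstra's algorithm on a dense matrix of
// edge lengths (len[i][j] = 1/weight; non-finite = edge absent). O(V^2)
// per source, which beats heap-based variants on the small dense graphs
// used here. Unreachable pairs come back as +Inf.
// [[Rcpp::export]]
NumericMatrix all_pairs_dijkstra(NumericMatrix len) {
  const int n = len.nrow();
  NumericMatrix out(n, n);
  std::vector<double> dist(n);
  std::vector<bool> done(n);
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < n; ++i) { dist[i] = R_PosInf; done[i] = false; }
    dist[s] = 0.0;
    for (int iter = 0; iter < n; ++iter) {
      int u = -1;
      double best = R_PosInf;
      for (int i = 0; i < n; ++i)
        if (!done[i] && dist[i] < best) { best = dist[i]; u = i; }
      if (u < 0) break;
      done[u] = true;
      const double du = dist[u];
      for (int v = 0; v < n; ++v) {
        const double l = len(u, v);
        if (!done[v] && R_finite(l) && du + l < dist[v]) dist[v] = du + l;
      }
    }
    for (int i = 0; i < n; ++i) out(s, i) = dist[i];
  }
  return out;
}
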