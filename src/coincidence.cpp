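#include <Rcpp.h>
using namespace Rcpp;

// Greedy one-to-one coincidence matching between two sorted spike trains.
// Each reference spike, taken in time order, is matched to the nearest
// still-unmatched target spike within +/- window seconds (ties -> earlier).
// [[Rcpp::export(name = ".count_coincidences_cpp")]]
int count_coincidences_cpp(NumericVector ref, NumericVector target, double window) {
  int nr = ref.size(), nt = target.size();
  if (nr == 0 || nt == 0) return 0;
  std::vector<bool> used(nt, false);
  int count = 0;
  int lo = 0;
  for (int i = 0; i < nr; ++i) {
    double t = ref[i];
    while (lo < nt && (used[lo] || target[lo] < t - window)) {
      if (!used[lo] && target[lo] >= t - window) break;
      ++lo;
    }
    int best = -1;
    double bestd = window + 1.0;
    for (int j = lo; j < nt && target[j] <= t + window; ++j) {
      if (used[j]) continue;
      double d = std::abs(target[j] - t);
      if (d <= window && d < bestd) { bestd = d; best = j; }
    }
    if (best >= 0) { used[best] = true; ++count; }
  }
  return count;
}

// Cross-electrode artifact scan. Spikes (sorted by time) are grouped into
// clusters by gaps <= tol; within a cluster, electrodes forming a connected
// set of more than two nodes in the adjacency graph have all their cluster
// spikes flagged for removal.
// [[Rcpp::export(name = ".artifact_flags_cpp")]]
LogicalVector artifact_flags_cpp(NumericVector t, IntegerVector elec_idx,
                                 LogicalMatrix adj, double tol) {
  int n = t.size();
  LogicalVector remove(n, false);
  int ne = adj.nrow();
  int start = 0;
  for (int i = 1; i <= n; ++i) {
    if (i == n || t[i] - t[i - 1] > tol) {
      int len = i - start;
      if (len >= 3) {
        // distinct electrodes in cluster
        std::vector<int> elecs;
        for (int k = start; k < i; ++k) {
          int e = elec_idx[k];
          if (std::find(elecs.begin(), elecs.end(), e) == elecs.end())
            elecs.push_back(e);
        }
        int m = elecs.size();
        if (m >= 3) {
          // connected components among elecs under adj
          std::vector<int> comp(m, -1);
          int nc = 0;
          for (int s = 0; s < m; ++s) {
            if (comp[s] >= 0) continue;
            comp[s] = nc;
            std::vector<int> stack(1, s);
            while (!stack.empty()) {
              int u = stack.back(); stack.pop_back();
              for (int v = 0; v < m; ++v) {
                if (comp[v] < 0 && elecs[u] < ne && elecs[v] < ne &&
                    adj(elecs[u], elecs[v])) {
                  comp[v] = nc;
                  stack.push_back(v);
                }
              }
            }
            ++nc;
          }
          std::vector<int> csize(nc, 0);
          for (int s = 0; s < m; ++s) csize[comp[s]]++;
          for (int k = start; k < i; ++k) {
            int e = elec_idx[k];
            for (int s = 0; s < m; ++s) {
              if (elecs[s] == e && csize[comp[s]] >= 3) { remove[k] = true; break; }
            }
          }
        }
      }
      start = i;
    }
  }
  return remove;
}
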