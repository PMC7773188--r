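#include <Rcpp.h>
using namespace Rcpp;

// Closed epsilon-neighbourhoods (self included) under Euclidean distance.
// Returns 1-based index vectors, one per row of X, each sorted increasing
// so downstream expansion is deterministic in row order.
// [[Rcpp::export]]
List eps_neighbours_cpp(NumericMatrix X, double eps) {
  const int n = X.nrow(), d = X.ncol();
  const double eps2 = eps * eps;
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) nb[i].push_back(i + 1);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = X(i, k) - X(j, k);
        s += diff * diff;
        if (s > eps2) break;
      }
      if (s <= eps2) {
        nb[i].push_back(j + 1);
        nb[j].push_back(i + 1);
      }
    }
  }
  List out(n);
  for (int i = 0; i < n; ++i)
    out[i] = IntegerVector(nb[i].begin(), nb[i].end());
  return out;
}

// Classic DBSCAN labelling from precomputed neighbour lists. A point is
// core iff its closed neighbourhood holds >= min_pts points. Expansion
// proceeds in row order from the first unlabelled core point, so border
// points reachable from several clusters go to the first cluster that
// claims them; labels are 1, 2, ... in order of discovery, 0 = noise.
// [[Rcpp::export]]
IntegerVector dbscan_from_neighbours_cpp(List nb, int min_pts) {
  const int n = nb.size();
  IntegerVector labels(n, 0);
  std::vector<bool> core(n);
  for (int i = 0; i < n; ++i)
    core[i] = (as<IntegerVector>(nb[i]).size() >= (R_xlen_t)min_pts);
  int cl = 0;
  std::deque<int> queue;
  for (int i = 0; i < n; ++i) {
    if (labels[i] != 0 || !core[i]) continue;
    ++cl;
    labels[i] = cl;
    queue.clear();
    queue.push_back(i);
    while (!queue.empty()) {
      const int p = queue.front();
      queue.pop_front();
      IntegerVector nbp = nb[p];
      for (R_xlen_t q = 0; q < nbp.size(); ++q) {
        const int j = nbp[q] - 1;
        if (labels[j] == 0) {
          labels[j] = cl;
          if (core[j]) queue.push_back(j);
        }
      }
    }
  }
  return labels;
}
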