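#include <Rcpp.h>
using namespace Rcpp;

// Threshold-free cluster enhancement of a statistic map on an adjacency
// graph: tfce[j] = sum_h extent(cluster_h(j))^E * h^H * step, accumulated
// over thresholds h = step, 2*step, ... for both signs.
//
// adj: list of integer vectors (1-based neighbor indices per element).
// [[Rcpp::export]]
NumericVector tfce_transform_cpp(const NumericVector& tmap, const List& adj,
                                 double E, double H, double step) {
  const int n = tmap.size();
  NumericVector out(n);
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nb[i].assign(v.begin(), v.end());
  }
  std::vector<int> label(n), stack, members;
  for (int sign = 0; sign < 2; ++sign) {
    double smax = 0.0;
    for (int i = 0; i < n; ++i) {
      double v = sign ? -tmap[i] : tmap[i];
      if (v > smax) smax = v;
    }
    if (smax <= 0.0) continue;
    int nthr = (int)std::floor(smax / step + 1e-12);
    for (int t = 1; t <= nthr; ++t) {
      double h = t * step;
      std::fill(label.begin(), label.end(), 0);
      for (int i = 0; i < n; ++i) {
        double vi = sign ? -tmap[i] : tmap[i];
        if (vi < h || label[i]) continue;
        // flood fill the cluster containing i
        members.clear();
        stack.clear();
        stack.push_back(i);
        label[i] = 1;
        while (!stack.empty()) {
          int u = stack.back(); stack.pop_back();
          members.push_back(u);
          for (int w1 : nb[u]) {
            int w = w1 - 1;
            double vw = sign ? -tmap[w] : tmap[w];
            if (vw >= h && !label[w]) { label[w] = 1; stack.push_back(w); }
          }
        }
        double inc = std::pow((double)members.size(), E) * std::pow(h, H) * step;
        if (sign) inc = -inc;
        for (int m : members) out[m] += inc;
      }
    }
  }
  return out;
}
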