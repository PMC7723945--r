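#include <Rcpp.h>
using namespace Rcpp;

// Exact brute-force nearest neighbour between 3D point sets.
// Mesh sizes in this package (<= ~1e4 vertices) make O(N*M) cheaper and
// simpler than a tree; results are exact, ties broken by lowest index.

// [[Rcpp::export(name = ".nn_points")]]
List nn_points(NumericMatrix query, NumericMatrix target) {
  const int nq = query.nrow(), nt = target.nrow();
  if (query.ncol() != 3 || target.ncol() != 3)
    stop("point matrices must have 3 columns");
  if (nt == 0) stop("target point set is empty");
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf;
    int best_j = 0;
    for (int j = 0; j < nt; ++j) {
      const double dx = target(j, 0) - qx;
      const double dy = target(j, 1) - qy;
      const double dz = target(j, 2) - qz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; best_j = j; }
    }
    idx[i] = best_j + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
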