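#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

// Multi-source Dijkstra on the full 8-connected lattice graph.
// Nodes are all grid squares (nrow x ncol); edge weights are 1 for
// orthogonal and sqrt(2) for diagonal moves, in pitch units. Every
// square is traversable: the domain is not an obstacle, so the result
// is the octile distance to the nearest source.
//
// sources: 0-based linear indices in raster order (row * ncol + col).
// Returns the distance of every square in the same raster order.
// [[Rcpp::export]]
Rcpp::NumericVector lattice_msd(int nrow, int ncol, Rcpp::IntegerVector sources) {
  const double SQ2 = std::sqrt(2.0);
  const long n = (long)nrow * ncol;
  std::vector<double> dist(n, R_PosInf);
  typedef std::pair<double, long> QE; // (distance, node)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;

  for (int k = 0; k < sources.size(); ++k) {
    long s = sources[k];
    if (s < 0 || s >= n) Rcpp::stop("source index out of range");
    if (dist[s] > 0.0) { dist[s] = 0.0; pq.push(QE(0.0, s)); }
  }

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first;
    long u = top.second;
    if (d > dist[u]) continue; // stale entry
    int r = (int)(u / ncol), c = (int)(u % ncol);
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
      double w = (dr[k] != 0 && dc[k] != 0) ? SQ2 : 1.0;
      long v = (long)rr * ncol + cc;
      double nd = d + w;
      if (nd < dist[v] - 1e-15) {
        dist[v] = nd;
        pq.push(QE(nd, v));
      }
    }
  }
  return Rcpp::NumericVector(dist.begin(), dist.end());
}
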