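#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Dijkstra shortest path on the 26-connected voxel graph.
// Edge cost between voxels u, v:
//   ((1/(I(u)+eps) + 1/(I(v)+eps)) / 2) * physical_step_length(u, v)
// Ties on distance are broken by smaller linear voxel index so the result is
// deterministic regardless of insertion order.
// intensities: column-major array of length nx*ny*nz; start/end 0-based.
// [[Rcpp::export]]
IntegerMatrix dijkstra_brightest_path(NumericVector intensities,
                                      IntegerVector dims,
                                      NumericVector spacing,
                                      IntegerVector start,
                                      IntegerVector end,
                                      double eps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  std::vector<double> inv(n);
  for (long i = 0; i < n; ++i) inv[i] = 1.0 / (intensities[i] + eps);

  // neighbor offsets and physical step lengths
  int offs[26][3];
  double step[26];
  int m = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        offs[m][0] = dx; offs[m][1] = dy; offs[m][2] = dz;
        step[m] = std::sqrt(dx * sx * dx * sx + dy * sy * dy * sy +
                            dz * sz * dz * sz);
        ++m;
      }

  const long s = start[0] + (long)nx * (start[1] + (long)ny * start[2]);
  const long t = end[0] + (long)nx * (end[1] + (long)ny * end[2]);

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(n, INF);
  std::vector<long> prev(n, -1);
  std::vector<char> done(n, 0);

  typedef std::pair<double, long> Node;  // (distance, linear index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  dist[s] = 0.0;
  pq.push(Node(0.0, s));

  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    long u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    if (u == t) break;
    int ux = (int)(u % nx);
    int uy = (int)((u / nx) % ny);
    int uz = (int)(u / ((long)nx * ny));
    double du = dist[u], iu = inv[u];
    for (int k = 0; k < 26; ++k) {
      int vx = ux + offs[k][0], vy = uy + offs[k][1], vz = uz + offs[k][2];
      if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz)
        continue;
      long v = vx + (long)nx * (vy + (long)ny * vz);
      if (done[v]) continue;
      double nd = du + 0.5 * (iu + inv[v]) * step[k];
      // strict improvement, or equal cost through a lexicographically
      // smaller predecessor: deterministic tie-break
      if (nd < dist[v] || (nd == dist[v] && prev[v] >= 0 && u < prev[v])) {
        dist[v] = nd;
        prev[v] = u;
        pq.push(Node(nd, v));
      }
    }
  }

  if (!std::isfinite(dist[t]))
    stop("no path between the requested endpoints");

  std::vector<long> path;
  for (long u = t; u != -1; u = prev[u]) path.push_back(u);
  std::reverse(path.begin(), path.end());

  IntegerMatrix out(path.size(), 3);
  for (size_t i = 0; i < path.size(); ++i) {
    long u = path[i];
    out(i, 0) = (int)(u % nx) + 1;
    out(i, 1) = (int)((u / nx) % ny) + 1;
    out(i, 2) = (int)(u / ((long)nx * ny)) + 1;
  }
  return out;
}
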