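#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra over the 26-connected voxel graph.
// domain: voxels that paths may traverse (roi plus sources);
// sources: distance-zero seeds; edge weight = Euclidean distance between
// voxel centres in mm. Returns R_PosInf for unreachable domain voxels and
// NA for voxels outside the domain.
// [[Rcpp::export(name = ".geodesic_dijkstra")]]
NumericVector geodesic_dijkstra(LogicalVector domain, LogicalVector sources,
                                IntegerVector dims, NumericVector voxmm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (domain.size() != n || sources.size() != n)
    stop("geodesic: dimension mismatch");

  // 26 neighbour offsets with precomputed metric weights
  std::vector<int> odx, ody, odz;
  std::vector<double> ow;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        odx.push_back(dx); ody.push_back(dy); odz.push_back(dz);
        double w = std::sqrt(dx * dx * voxmm[0] * voxmm[0] +
                             dy * dy * voxmm[1] * voxmm[1] +
                             dz * dz * voxmm[2] * voxmm[2]);
        ow.push_back(w);
      }

  std::vector<double> dist(n, R_PosInf);
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (R_xlen_t i = 0; i < n; ++i)
    if (sources[i]) { dist[i] = 0.0; pq.push(Node(0.0, i)); }

  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    const double d = top.first;
    const R_xlen_t i = top.second;
    if (d > dist[i]) continue;
    const int iz = (int)(i / sxy);
    const int iy = (int)((i - (R_xlen_t)iz * sxy) / nx);
    const int ix = (int)(i - (R_xlen_t)iz * sxy - (R_xlen_t)iy * nx);
    for (size_t k = 0; k < odx.size(); ++k) {
      const int jx = ix + odx[k], jy = iy + ody[k], jz = iz + odz[k];
      if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
        continue;
      const R_xlen_t j = (R_xlen_t)jz * sxy + (R_xlen_t)jy * nx + jx;
      if (!domain[j]) continue;
      const double nd = d + ow[k];
      if (nd < dist[j]) { dist[j] = nd; pq.push(Node(nd, j)); }
    }
  }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (domain[i] || sources[i]) ? dist[i] : NA_REAL;
  return out;
}
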