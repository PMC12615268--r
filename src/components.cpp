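#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Neighbour offsets for a 2D (4/8) or 3D (6/18/26) grid.
// Offsets are expressed in (i1, i2, i3) index space; i3 is 0 in 2D.
static std::vector<std::array<int,3>> neighbour_offsets(int ndim, int connectivity) {
  std::vector<std::array<int,3>> offs;
  if (ndim == 2) {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b) {
        if (a == 0 && b == 0) continue;
        int manh = std::abs(a) + std::abs(b);
        if (connectivity == 4 && manh > 1) continue;
        offs.push_back({a, b, 0});
      }
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          int manh = std::abs(a) + std::abs(b) + std::abs(c);
          if (connectivity == 6 && manh > 1) continue;
          if (connectivity == 18 && manh > 2) continue;
          offs.push_back({a, b, c});
        }
  }
  return offs;
}

// Label connected components of the non-zero voxels of `x`.
// Two voxels are connected only if adjacent AND carry the same input value,
// so a label image can be re-split per object in a single pass.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(IntegerVector x, int connectivity) {
  IntegerVector dims = x.attr("dim");
  int ndim = dims.size();
  if (ndim != 2 && ndim != 3)
    stop("connected components: array must be 2D or 3D");
  int n1 = dims[0], n2 = dims[1], n3 = (ndim == 3) ? dims[2] : 1;
  R_xlen_t n = x.size();
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  std::vector<std::array<int,3>> offs =
    neighbour_offsets(ndim, connectivity);
  std::vector<R_xlen_t> stack;
  int next_id = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (x[s] == 0 || lab[s] != 0) continue;
    ++next_id;
    int value = x[s];
    lab[s] = next_id;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i1 = (int)(cur % n1);
      int i2 = (int)((cur / n1) % n2);
      int i3 = (int)(cur / ((R_xlen_t)n1 * n2));
      for (const auto& o : offs) {
        int j1 = i1 + o[0], j2 = i2 + o[1], j3 = i3 + o[2];
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 ||
            j3 < 0 || j3 >= n3) continue;
        R_xlen_t q = (R_xlen_t)j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
        if (x[q] == value && lab[q] == 0) {
          lab[q] = next_id;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Multi-source Dijkstra travel time on the 8-connected pixel graph of a 2D
// mask, with Euclidean edge weights (1 or sqrt(2)). Sources are 1-based
// linear indices held at time 0. Background and unreachable pixels -> Inf.
// [[Rcpp::export(name = ".geodesic_dijkstra")]]
NumericVector geodesic_dijkstra(IntegerVector mask, IntegerVector sources) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 2) stop("geodesic distance: mask must be 2D");
  int n1 = dims[0], n2 = dims[1];
  R_xlen_t n = mask.size();
  NumericVector dist(n, R_PosInf);
  dist.attr("dim") = dims;
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node>> pq;
  for (R_xlen_t k = 0; k < sources.size(); ++k) {
    R_xlen_t s = sources[k] - 1;
    if (s < 0 || s >= n) stop("source index out of range");
    if (mask[s] == 0) stop("source pixel lies outside the mask");
    dist[s] = 0.0;
    pq.push({0.0, s});
  }
  const double SQ2 = std::sqrt(2.0);
  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d = top.first;
    R_xlen_t cur = top.second;
    if (d > dist[cur]) continue;
    int i1 = (int)(cur % n1), i2 = (int)(cur / n1);
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b) {
        if (a == 0 && b == 0) continue;
        int j1 = i1 + a, j2 = i2 + b;
        if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2) continue;
        R_xlen_t q = (R_xlen_t)j1 + (R_xlen_t)n1 * j2;
        if (mask[q] == 0) continue;
        double w = (a != 0 && b != 0) ? SQ2 : 1.0;
        if (d + w < dist[q]) {
          dist[q] = d + w;
          pq.push({d + w, q});
        }
      }
  }
  return dist;
}
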