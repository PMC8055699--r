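#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// 8-neighbourhood offsets (row, col) and the index of the diagonal ones.
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Geodesic distance transform on a binary mask.
//
// Multi-source Dijkstra over the pixel graph restricted to mask==TRUE,
// 8-connected, with step weights sy (vertical), sx (horizontal) and
// sqrt(sy^2 + sx^2) (diagonal). `seeds` are 1-based linear indices
// (column-major, as R stores matrices). Pixels off the mask or unreachable
// get +Inf.
// [[Rcpp::export]]
NumericMatrix cpp_geodesic_dt(LogicalMatrix mask, IntegerVector seeds,
                              double sy, double sx) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double diag = std::sqrt(sy * sy + sx * sx);
  const double w[3] = {sx, sy, diag};  // indexed by |dr| + |dc| - 1 ... see below
  NumericMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), R_PosInf);

  typedef std::pair<double, int> Node;  // (distance, linear index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  for (int i = 0; i < seeds.size(); ++i) {
    int idx = seeds[i] - 1;
    if (idx < 0 || idx >= nr * nc) stop("seed index out of range");
    if (!mask[idx]) stop("seed pixel is not on the mask");
    if (dist[idx] > 0) {
      dist[idx] = 0.0;
      pq.push(Node(0.0, idx));
    }
  }

  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    const double d = top.first;
    const int idx = top.second;
    if (d > dist[idx]) continue;  // stale entry
    const int r = idx % nr, c = idx / nr;
    for (int k = 0; k < 8; ++k) {
      const int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int jdx = rr + cc * nr;
      if (!mask[jdx]) continue;
      const int wi = std::abs(DR[k]) + std::abs(DC[k]) - 1;  // 0=horiz,1=vert? no:
      // |dr|+|dc| is 1 for axial, 2 for diagonal; distinguish axial direction:
      double step;
      if (wi == 1) step = w[2];
      else step = (DR[k] != 0) ? sy : sx;
      const double nd = d + step;
      if (nd < dist[jdx]) {
        dist[jdx] = nd;
        pq.push(Node(nd, jdx));
      }
    }
  }
  return dist;
}

// Shortest 8-connected path between two mask pixels (1-based linear indices).
// Dijkstra with predecessor tracking; returns the path as 1-based linear
// indices from `from` to `to`, or an empty vector if unreachable.
// [[Rcpp::export]]
IntegerVector cpp_geodesic_path(LogicalMatrix mask, int from, int to,
                                double sy, double sx) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double diag = std::sqrt(sy * sy + sx * sx);
  const int n = nr * nc;
  if (from < 1 || from > n || to < 1 || to > n) stop("endpoint index out of range");
  const int s = from - 1, t = to - 1;
  if (!mask[s] || !mask[t]) stop("endpoint pixel is not on the mask");

  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  std::vector<int> pred(n, -1);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  dist[s] = 0.0;
  pq.push(Node(0.0, s));

  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    const double d = top.first;
    const int idx = top.second;
    if (d > dist[idx]) continue;
    if (idx == t) break;
    const int r = idx % nr, c = idx / nr;
    for (int k = 0; k < 8; ++k) {
      const int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int jdx = rr + cc * nr;
      if (!mask[jdx]) continue;
      double step;
      if (DR[k] != 0 && DC[k] != 0) step = diag;
      else step = (DR[k] != 0) ? sy : sx;
      const double nd = d + step;
      if (nd < dist[jdx]) {
        dist[jdx] = nd;
        pred[jdx] = idx;
        pq.push(Node(nd, jdx));
      }
    }
  }

  if (!std::isfinite(dist[t])) return IntegerVector(0);
  std::vector<int> rev;
  for (int cur = t; cur != -1; cur = pred[cur]) rev.push_back(cur + 1);
  IntegerVector path(rev.size());
  for (size_t i = 0; i < rev.size(); ++i) path[i] = rev[rev.size() - 1 - i];
  return path;
}

// Connected-component labelling of a binary mask (flood fill).
// connectivity is 4 or 8. Labels are assigned in row-major raster order of
// each component's first pixel, i.e. topmost-then-leftmost; background
// stays 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const int idx = r + c * nr;
      if (!mask[idx] || lab[idx] != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(idx);
      lab[idx] = next;
      while (!stack.empty()) {
        const int cur = stack.back();
        stack.pop_back();
        const int cr = cur % nr, cc2 = cur / nr;
        for (int k = 0; k < 8; ++k) {
          if (connectivity == 4 && DR[k] != 0 && DC[k] != 0) continue;
          const int rr = cr + DR[k], ccc = cc2 + DC[k];
          if (rr < 0 || rr >= nr || ccc < 0 || ccc >= nc) continue;
          const int jdx = rr + ccc * nr;
          if (mask[jdx] && lab[jdx] == 0) {
            lab[jdx] = next;
            stack.push_back(jdx);
          }
        }
      }
    }
  }
  return lab;
}
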