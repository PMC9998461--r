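// Binary-mask geometry: iterative morphological thinning (Zhang-Suen),
// longest skeleton path by double breadth-first traversal, and even-odd
// polygon rasterization with pixel-center inclusion.
//
// Masks are IntegerMatrix (rows = y, cols = x) with values {0,1}.
// Points returned to R are 0-based (x, y).
#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cg_thin(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix img = clone(mask);
  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= H || j < 0 || j >= W) return 0;
    return img(i, j);
  };
  bool changed = true;
  std::vector<std::pair<int, int>> del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int i = 0; i < H; ++i) {
        for (int j = 0; j < W; ++j) {
          if (!img(i, j)) continue;
          // neighbours clockwise from north: P2..P9
          int p[8] = {at(i - 1, j), at(i - 1, j + 1), at(i, j + 1),
                      at(i + 1, j + 1), at(i + 1, j), at(i + 1, j - 1),
                      at(i, j - 1), at(i - 1, j - 1)};
          int B = 0, A = 0;
          for (int k = 0; k < 8; ++k) {
            B += p[k];
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++A;
          }
          if (B < 2 || B > 6 || A != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;   // P2*P4*P6
            if (p[2] * p[4] * p[6] != 0) continue;   // P4*P6*P8
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;   // P2*P4*P8
            if (p[0] * p[4] * p[6] != 0) continue;   // P2*P6*P8
          }
          del.push_back({i, j});
        }
      }
      if (!del.empty()) changed = true;
      for (auto& d : del) img(d.first, d.second) = 0;
    }
  }
  return img;
}

static std::vector<int> bfs_far(const IntegerMatrix& sk, int start,
                                std::vector<int>& parent, int& far) {
  const int H = sk.nrow(), W = sk.ncol();
  std::vector<int> dist((size_t)H * W, -1);
  parent.assign((size_t)H * W, -1);
  std::queue<int> q;
  dist[start] = 0;
  q.push(start);
  far = start;
  while (!q.empty()) {
    int v = q.front(); q.pop();
    int i = v % H, j = v / H;
    if (dist[v] > dist[far]) far = v;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (!di && !dj) continue;
        int ii = i + di, jj = j + dj;
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        if (!sk(ii, jj)) continue;
        int u = jj * H + ii;
        if (dist[u] >= 0) continue;
        dist[u] = dist[v] + 1;
        parent[u] = v;
        q.push(u);
      }
  }
  return dist;
}

// Longest simple path across the skeleton's BFS spanning tree: BFS from any
// pixel to the farthest pixel u, then BFS from u; the parent chain from the
// new farthest pixel back to u is returned, ordered from u.
// Assumes all foreground pixels form one 8-connected component.
// [[Rcpp::export]]
IntegerMatrix cg_longest_path(const IntegerMatrix& sk) {
  const int H = sk.nrow(), W = sk.ncol();
  int start = -1;
  for (int j = 0; j < W && start < 0; ++j)
    for (int i = 0; i < H; ++i)
      if (sk(i, j)) { start = j * H + i; break; }
  if (start < 0) return IntegerMatrix(0, 2);
  std::vector<int> parent;
  int u, v;
  bfs_far(sk, start, parent, u);
  bfs_far(sk, u, parent, v);
  std::vector<int> path;
  for (int w = v; w != -1; w = parent[w]) path.push_back(w);
  // path currently v -> u; reverse so it starts at u
  IntegerMatrix out(path.size(), 2);
  for (size_t k = 0; k < path.size(); ++k) {
    int w = path[path.size() - 1 - k];
    out(k, 0) = w / H;   // x
    out(k, 1) = w % H;   // y
  }
  return out;
}

// Even-odd rasterization of one or more rings onto an H x W grid.
// A pixel (row i, col j) is foreground when its center (j + 0.5, i + 0.5)
// has an odd crossing number over all rings. Half-open edge rule
// min(y) <= yc < max(y) avoids double-counting vertices.
// [[Rcpp::export]]
IntegerMatrix cg_rasterize(const List& rings, int H, int W) {
  IntegerMatrix mask(H, W);
  for (int i = 0; i < H; ++i) {
    const double yc = i + 0.5;
    std::vector<double> xs;
    for (int r = 0; r < rings.size(); ++r) {
      NumericMatrix ring = rings[r];
      const int n = ring.nrow();
      if (n < 3) continue;
      for (int a = 0; a < n; ++a) {
        const int b = (a + 1) % n;
        double x1 = ring(a, 0), y1 = ring(a, 1);
        double x2 = ring(b, 0), y2 = ring(b, 1);
        if (y1 == y2) continue;
        if ((y1 <= yc && yc < y2) || (y2 <= yc && yc < y1))
          xs.push_back(x1 + (yc - y1) / (y2 - y1) * (x2 - x1));
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int j0 = (int)std::ceil(xs[k] - 0.5);
      int j1 = (int)std::floor(xs[k + 1] - 0.5 - 1e-12);
      // pixel centers j + 0.5 in [xs[k], xs[k+1])
      if (j0 < 0) j0 = 0;
      if (j1 >= W) j1 = W - 1;
      for (int j = j0; j <= j1; ++j) mask(i, j) = 1;
    }
  }
  return mask;
}
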