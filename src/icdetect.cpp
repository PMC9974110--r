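#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <queue>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Connected components (4-connectivity) on a logical matrix.
// Returns an integer matrix of labels, 0 = background, components 1..k.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix &mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({y, x});
      lab(y, x) = next;
      while (!stack.empty()) {
        auto [cy, cx] = stack.back();
        stack.pop_back();
        const int dy[4] = {-1, 1, 0, 0};
        const int dx[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int ny = cy + dy[k], nx = cx + dx[k];
          if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
          if (mask(ny, nx) && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            stack.push_back({ny, nx});
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Moore-neighbour boundary tracing of one labeled component.
// Returns an m x 2 matrix of (x, y) pixel coordinates (1-based, matrix
// row = y, col = x) tracing the outer boundary clockwise.
// [[Rcpp::export(name = ".trace_boundary")]]
IntegerMatrix trace_boundary(const IntegerMatrix &lab, int id) {
  int h = lab.nrow(), w = lab.ncol();
  auto inside = [&](int y, int x) {
    return y >= 0 && y < h && x >= 0 && x < w && lab(y, x) == id;
  };
  int sy = -1, sx = -1;
  for (int x = 0; x < w && sy < 0; ++x)
    for (int y = 0; y < h; ++y)
      if (lab(y, x) == id) { sy = y; sx = x; break; }
  if (sy < 0) return IntegerMatrix(0, 2);
  // Moore neighbourhood in clockwise order starting from W.
  const int my[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int mx[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  std::vector<std::pair<int, int>> path;
  int cy = sy, cx = sx;
  int backtrack = 0;  // came from the west
  path.push_back({cy, cx});
  for (int guard = 0; guard < 4 * (h * w + 1); ++guard) {
    bool moved = false;
    for (int k = 0; k < 8; ++k) {
      int dir = (backtrack + k) % 8;
      int ny = cy + my[dir], nx = cx + mx[dir];
      if (inside(ny, nx)) {
        backtrack = (dir + 5) % 8;  // re-enter from the previous cell's side
        cy = ny; cx = nx;
        moved = true;
        break;
      }
    }
    if (!moved) break;                      // isolated pixel
    if (cy == sy && cx == sx) break;        // loop closed
    path.push_back({cy, cx});
  }
  IntegerMatrix out(path.size(), 2);
  for (size_t i = 0; i < path.size(); ++i) {
    out(i, 0) = path[i].second + 1;  // x
    out(i, 1) = path[i].first + 1;   // y
  }
  return out;
}

// ---------------------------------------------------------------------------
// im2col for a 3x3 same-padded convolution on an (H, W, C, N) tensor.
// Output rows ordered (h fastest, then w, then n); columns ordered
// (dy fastest, then dx, then c), matching the kernel matrix layout.
// [[Rcpp::export(name = ".im2col3")]]
NumericMatrix im2col3(const NumericVector &X, int H, int W, int C, int N) {
  NumericMatrix out(H * W * N, 9 * C);
  const double *x = X.begin();
  double *o = out.begin();
  const R_xlen_t plane = (R_xlen_t)H * W;
  const R_xlen_t vol = plane * C;
  for (int c = 0; c < C; ++c) {
    for (int dx = 0; dx < 3; ++dx) {
      for (int dy = 0; dy < 3; ++dy) {
        int col = c * 9 + dx * 3 + dy;
        double *oc = o + (R_xlen_t)col * H * W * N;
        for (int n = 0; n < N; ++n) {
          const double *xc = x + (R_xlen_t)n * vol + (R_xlen_t)c * plane;
          double *on = oc + (R_xlen_t)n * plane;
          for (int ow = 0; ow < W; ++ow) {
            int sx = ow + dx - 1;  // source column (0-based)
            double *op = on + (R_xlen_t)ow * H;
            if (sx < 0 || sx >= W) {
              std::fill(op, op + H, 0.0);
              continue;
            }
            const double *xp = xc + (R_xlen_t)sx * H;
            // source row = oh + dy - 1
            if (dy == 1) {
              std::copy(xp, xp + H, op);
            } else if (dy == 0) {
              op[0] = 0.0;
              std::copy(xp, xp + H - 1, op + 1);
            } else {
              std::copy(xp + 1, xp + H, op);
              op[H - 1] = 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Random forest (binary classification, Gini CART, bootstrap + mtry).
// Trees are stored as flat parallel arrays for cheap serialization.

struct TreeBuf {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right; // 0-based node ids, -1 for leaf
  std::vector<double> prob;     // P(class 1) in the node
};

static void grow_node(const NumericMatrix &X, const IntegerVector &y,
                      std::vector<int> &idx, int lo, int hi, int depth,
                      int mtry, int max_depth, int min_node,
                      std::mt19937 &rng, TreeBuf &tb, int node_id) {
  int n = hi - lo;
  int pos = 0;
  for (int i = lo; i < hi; ++i) pos += y[idx[i]];
  double p1 = (double)pos / n;
  tb.prob[node_id] = p1;
  bool pure = (pos == 0 || pos == n);
  if (pure || n < 2 * min_node || (max_depth > 0 && depth >= max_depth)) return;

  int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  std::shuffle(feats.begin(), feats.end(), rng);

  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<std::pair<double, int>> vals(n);
  double parent_gini = 2.0 * p1 * (1.0 - p1) * n;

  int tried = 0;
  for (int fj = 0; fj < p && tried < mtry; ++fj) {
    int f = feats[fj];
    for (int i = 0; i < n; ++i)
      vals[i] = {X(idx[lo + i], f), y[idx[lo + i]]};
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;  // constant feature
    ++tried;
    int lpos = 0;
    for (int i = 0; i < n - 1; ++i) {
      lpos += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      int ln = i + 1, rn = n - ln;
      int rpos = pos - lpos;
      double gl = 2.0 * lpos * (ln - lpos) / (double)ln;
      double gr = 2.0 * rpos * (rn - rpos) / (double)rn;
      double gain = parent_gini - gl - gr;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return;

  // Partition idx[lo:hi) in place.
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return;  // numerically degenerate

  int l_id = tb.feature.size(), r_id = l_id + 1;
  for (int k = 0; k < 2; ++k) {
    tb.feature.push_back(-1);
    tb.thr.push_back(0.0);
    tb.left.push_back(-1);
    tb.right.push_back(-1);
    tb.prob.push_back(0.0);
  }
  tb.feature[node_id] = best_f;
  tb.thr[node_id] = best_thr;
  tb.left[node_id] = l_id;
  tb.right[node_id] = r_id;
  grow_node(X, y, idx, lo, mid, depth + 1, mtry, max_depth, min_node, rng, tb, l_id);
  grow_node(X, y, idx, mid, hi, depth + 1, mtry, max_depth, min_node, rng, tb, r_id);
}

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit(const NumericMatrix &X, const IntegerVector &y, int n_trees,
            int mtry, int max_depth, int min_node, int seed) {
  int n = X.nrow();
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_int_distribution<int> pick(0, n - 1);
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    TreeBuf tb;
    tb.feature.assign(1, -1);
    tb.thr.assign(1, 0.0);
    tb.left.assign(1, -1);
    tb.right.assign(1, -1);
    tb.prob.assign(1, 0.0);
    grow_node(X, y, idx, 0, n, 0, mtry, max_depth, min_node, rng, tb, 0);
    trees[t] = List::create(
        _["feature"] = wrap(tb.feature), _["thr"] = wrap(tb.thr),
        _["left"] = wrap(tb.left), _["right"] = wrap(tb.right),
        _["prob"] = wrap(tb.prob));
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict(const List &trees, const NumericMatrix &X) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector thr = tr["thr"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector prob = tr["prob"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= thr[node]) ? left[node] : right[node];
      }
      out[i] += prob[node];
    }
  }
  return out / (double)T;
}
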