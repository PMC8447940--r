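#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Depth- and leaf-size-limited regression tree grown by exact greedy search
// over all features and midpoints between sorted unique values, maximizing the
// weighted SSE reduction of the gradient targets. Leaf values are Newton steps
// sum(w*r) / sum(h) with h = w*p*(1-p) supplied per row. Ties in the split
// search are broken toward the lowest feature index, then the lowest
// threshold (features and candidate thresholds are scanned in ascending order
// and only strictly better gains are accepted).

struct NodeTask {
  int node_id;
  int depth;
  int begin;
  int end; // half-open range into the row-index workspace
};

// [[Rcpp::export(name = ".grow_tree_cpp")]]
List grow_tree_cpp(NumericMatrix X, IntegerVector rows, NumericVector grad,
                   NumericVector w, NumericVector hess, int max_depth,
                   int min_leaf) {
  const int p = X.ncol();
  std::vector<int> idx(rows.begin(), rows.end()); // 0-based row indices

  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // NA for leaf
  std::vector<int> left, right;  // 0 when absent (converted to NA in R)
  std::vector<double> value;     // leaf Newton step (leaves only; 0 internal)
  std::vector<double> improvement;

  auto new_node = [&]() {
    feature.push_back(-1);
    threshold.push_back(NA_REAL);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    improvement.push_back(0.0);
    return (int)feature.size() - 1;
  };

  std::vector<NodeTask> stack;
  int root = new_node();
  stack.push_back({root, 0, 0, (int)idx.size()});

  std::vector<double> xv, gv, wv;
  std::vector<int> ord;

  while (!stack.empty()) {
    NodeTask t = stack.back();
    stack.pop_back();
    const int n = t.end - t.begin;

    // node totals
    double S = 0.0, W = 0.0, H = 0.0, G = 0.0;
    for (int i = t.begin; i < t.end; ++i) {
      const int r = idx[i];
      S += w[r] * grad[r];
      W += w[r];
      H += hess[r];
      G += w[r] * grad[r];
    }
    (void)G;

    bool make_leaf = (t.depth >= max_depth) || (n < 2 * min_leaf);
    int best_f = -1;
    double best_gain = 0.0, best_thr = NA_REAL;

    if (!make_leaf) {
      const double parent_score = (W > 0.0) ? S * S / W : 0.0;
      for (int f = 0; f < p; ++f) {
        xv.resize(n); gv.resize(n); wv.resize(n); ord.resize(n);
        for (int i = 0; i < n; ++i) {
          const int r = idx[t.begin + i];
          xv[i] = X(r, f);
          gv[i] = w[r] * grad[r];
          wv[i] = w[r];
          ord[i] = i;
        }
        std::stable_sort(ord.begin(), ord.end(),
                         [&](int a, int b) { return xv[a] < xv[b]; });
        double sl = 0.0, wl = 0.0;
        for (int i = 0; i < n - 1; ++i) {
          const int oi = ord[i];
          sl += gv[oi];
          wl += wv[oi];
          const double xa = xv[oi], xb = xv[ord[i + 1]];
          if (xa == xb) continue; // not between distinct values
          const int nl = i + 1, nr = n - nl;
          if (nl < min_leaf || nr < min_leaf) continue;
          const double wr_ = W - wl, sr = S - sl;
          if (wl <= 0.0 || wr_ <= 0.0) continue;
          const double gain = sl * sl / wl + sr * sr / wr_ - parent_score;
          if (gain > best_gain + 1e-15 && gain > 0.0) {
            best_gain = gain;
            best_f = f;
            best_thr = xa + 0.5 * (xb - xa);
          }
        }
      }
      if (best_f < 0) make_leaf = true;
    }

    if (make_leaf) {
      value[t.node_id] = (H < 1e-12) ? 0.0 : S / H;
      continue;
    }

    // partition rows in place: x < threshold goes left
    int mid = t.begin;
    for (int i = t.begin; i < t.end; ++i) {
      if (X(idx[i], best_f) < best_thr) {
        std::swap(idx[i], idx[mid]);
        ++mid;
      }
    }

    feature[t.node_id] = best_f;
    threshold[t.node_id] = best_thr;
    improvement[t.node_id] = best_gain;
    int l = new_node();
    int r = new_node();
    left[t.node_id] = l;
    right[t.node_id] = r;
    stack.push_back({r, t.depth + 1, mid, t.end});
    stack.push_back({l, t.depth + 1, t.begin, mid});
  }

  return List::create(
      _["feature"] = IntegerVector(feature.begin(), feature.end()),
      _["threshold"] = NumericVector(threshold.begin(), threshold.end()),
      _["left"] = IntegerVector(left.begin(), left.end()),
      _["right"] = IntegerVector(right.begin(), right.end()),
      _["value"] = NumericVector(value.begin(), value.end()),
      _["improvement"] = NumericVector(improvement.begin(), improvement.end()));
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericVector predict_tree_cpp(IntegerVector feature, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               NumericVector value, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) < threshold[node]) ? left[node] : right[node];
    }
    out[i] = value[node];
  }
  return out;
}
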