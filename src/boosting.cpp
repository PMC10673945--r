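// Gradient-boosted regression trees (squared loss, xgboost-style exact greedy
// split finding) plus a bagged random-forest variant used by the iterative
// imputer, and Saabas path attribution for feature importance.
//
// None of the usual tree packages (xgboost, gbm, rpart, ranger) are available
// in the target environment, so the learner is self-contained here. The
// objective follows the standard second-order formulation for squared loss:
// g_i = pred_i - y_i, h_i = 1, leaf weight = -G/(H + lambda),
// split gain = GL^2/(HL+l) + GR^2/(HR+l) - G^2/(H+l).

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Node {
  int feat = -1;          // -1 => leaf
  double thr = 0.0;       // goes left when x < thr
  int left = -1, right = -1;
  double value = 0.0;     // -G/(H+lambda), stored for every node (Saabas)
  double G = 0.0, H = 0.0;
};

struct TreeParams {
  int max_depth;
  double lambda;
  double min_child_weight;
  double colsample_bylevel;
  double min_gain;
};

// per-feature row order and values, both in ascending feature order, so the
// split scan reads values sequentially (cache-friendly)
struct SortedFeature {
  std::vector<int> idx;
  std::vector<double> val;
};

// Grow one tree level-wise. g/h are per-row gradient/hessian; rows with
// h[r] == 0 are out of the tree (not sampled). sorted_idx[j] holds all row
// indices ordered by feature j (precomputed once per fit). feat_set is the
// per-tree column sample.
std::vector<Node> grow_tree(const NumericMatrix& X,
                            const std::vector<double>& g,
                            const std::vector<double>& h,
                            const std::vector<SortedFeature>& sorted_feat,
                            const std::vector<int>& feat_set,
                            const TreeParams& par,
                            std::mt19937& rng) {
  const int n = X.nrow();
  std::vector<Node> nodes;
  std::vector<int> node_of(n, -1);

  Node root;
  for (int r = 0; r < n; ++r) {
    if (h[r] > 0.0) { root.G += g[r]; root.H += h[r]; node_of[r] = 0; }
  }
  root.value = -root.G / (root.H + par.lambda);
  nodes.push_back(root);

  std::vector<int> frontier(1, 0);

  for (int depth = 0; depth < par.max_depth && !frontier.empty(); ++depth) {
    const int nf = (int)frontier.size();
    // map node id -> slot in per-level scratch arrays
    std::vector<int> slot(nodes.size(), -1);
    for (int s = 0; s < nf; ++s) slot[frontier[s]] = s;

    // per-level column sample
    std::vector<int> feats = feat_set;
    if (par.colsample_bylevel < 1.0) {
      int keep = std::max(1, (int)std::round(par.colsample_bylevel * feats.size()));
      std::shuffle(feats.begin(), feats.end(), rng);
      feats.resize(keep);
      std::sort(feats.begin(), feats.end());
    }

    std::vector<double> best_gain(nf, par.min_gain);
    std::vector<int> best_feat(nf, -1);
    std::vector<double> best_thr(nf, 0.0);

    std::vector<double> GL(nf), HL(nf), prev_val(nf);
    std::vector<char> seen(nf);

    for (size_t fi = 0; fi < feats.size(); ++fi) {
      const int j = feats[fi];
      std::fill(GL.begin(), GL.end(), 0.0);
      std::fill(HL.begin(), HL.end(), 0.0);
      std::fill(seen.begin(), seen.end(), 0);
      const int* ord = sorted_feat[j].idx.data();
      const double* vals = sorted_feat[j].val.data();
      for (int k = 0; k < n; ++k) {
        const int r = ord[k];
        const int u = node_of[r];
        if (u < 0 || (size_t)u >= slot.size()) continue;
        const int s = slot[u];
        if (s < 0) continue;
        const double x = vals[k];
        if (seen[s] && x > prev_val[s]) {
          const double hl = HL[s], hr = nodes[u].H - hl;
          if (hl >= par.min_child_weight && hr >= par.min_child_weight) {
            const double gl = GL[s], gr = nodes[u].G - gl;
            const double gain = gl * gl / (hl + par.lambda)
                              + gr * gr / (hr + par.lambda)
                              - nodes[u].G * nodes[u].G / (nodes[u].H + par.lambda);
            if (gain > best_gain[s]) {
              best_gain[s] = gain;
              best_feat[s] = j;
              best_thr[s] = 0.5 * (prev_val[s] + x);
            }
          }
        }
        GL[s] += g[r]; HL[s] += h[r];
        prev_val[s] = x; seen[s] = 1;
      }
    }

    // split frontier nodes that found a usable split
    std::vector<int> next_frontier;
    for (int s = 0; s < nf; ++s) {
      const int u = frontier[s];
      if (best_feat[s] < 0) continue;  // stays a leaf
      Node L, R;
      nodes[u].feat = best_feat[s];
      nodes[u].thr = best_thr[s];
      nodes[u].left = (int)nodes.size();
      nodes[u].right = (int)nodes.size() + 1;
      nodes.push_back(L);
      nodes.push_back(R);
      next_frontier.push_back(nodes[u].left);
      next_frontier.push_back(nodes[u].right);
    }
    if (next_frontier.empty()) break;

    const double* Xp = X.begin();
    for (int r = 0; r < n; ++r) {
      int u = node_of[r];
      if (u < 0) continue;
      if (nodes[u].feat >= 0) {
        const int child = (Xp[(size_t)nodes[u].feat * n + r] < nodes[u].thr)
                            ? nodes[u].left : nodes[u].right;
        nodes[child].G += g[r];
        nodes[child].H += h[r];
        node_of[r] = child;
      } else {
        node_of[r] = -1;  // settled leaf: row no longer active
      }
    }
    for (size_t u = 0; u < nodes.size(); ++u) {
      if (nodes[u].H > 0.0 && nodes[u].left >= 0) {
        nodes[nodes[u].left].value =
          -nodes[nodes[u].left].G / (nodes[nodes[u].left].H + par.lambda);
        nodes[nodes[u].right].value =
          -nodes[nodes[u].right].G / (nodes[nodes[u].right].H + par.lambda);
      }
    }
    frontier.swap(next_frontier);
  }
  return nodes;
}

NumericMatrix pack_tree(const std::vector<Node>& nodes, double scale) {
  NumericMatrix M((int)nodes.size(), 6);
  for (size_t i = 0; i < nodes.size(); ++i) {
    M(i, 0) = nodes[i].feat;
    M(i, 1) = nodes[i].thr;
    M(i, 2) = nodes[i].left;
    M(i, 3) = nodes[i].right;
    M(i, 4) = nodes[i].value * scale;
    M(i, 5) = nodes[i].H;
  }
  colnames(M) = CharacterVector::create("feat", "thr", "left", "right",
                                        "value", "cover");
  return M;
}

double tree_predict_row(const NumericMatrix& M, const NumericMatrix& X, int r) {
  int u = 0;
  while (M(u, 0) >= 0) {
    u = (X(r, (int)M(u, 0)) < M(u, 1)) ? (int)M(u, 2) : (int)M(u, 3);
  }
  return M(u, 4);
}

std::vector<SortedFeature> presort(const NumericMatrix& X) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<SortedFeature> sorted_feat(p);
  for (int j = 0; j < p; ++j) {
    const double* col = X.begin() + (size_t)j * n;
    std::vector<int>& ord = sorted_feat[j].idx;
    ord.resize(n);
    for (int r = 0; r < n; ++r) ord[r] = r;
    std::stable_sort(ord.begin(), ord.end(), [col](int a, int b) {
      return col[a] < col[b];
    });
    sorted_feat[j].val.resize(n);
    for (int r = 0; r < n; ++r) sorted_feat[j].val[r] = col[ord[r]];
  }
  return sorted_feat;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_boost_fit")]]
List cpp_boost_fit(NumericMatrix X, NumericVector y,
                   int nrounds, double eta, int max_depth,
                   double subsample, double colsample_bytree,
                   double colsample_bylevel,
                   double lambda, double min_child_weight,
                   Nullable<NumericMatrix> Xval_, Nullable<NumericVector> yval_,
                   int early_stopping_rounds, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 1 || p < 1) stop("empty training matrix");
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  double base = 0.0;
  for (int i = 0; i < n; ++i) base += y[i];
  base /= n;

  const bool has_val = Xval_.isNotNull() && yval_.isNotNull();
  NumericMatrix Xval;
  NumericVector yval;
  int nval = 0;
  if (has_val) {
    Xval = NumericMatrix(Xval_);
    yval = NumericVector(yval_);
    nval = Xval.nrow();
  }

  std::vector<SortedFeature> sorted_feat = presort(X);
  std::vector<double> pred(n, base), predval(nval, base);
  std::vector<double> g(n), h(n);
  std::vector<int> all_feats(p);
  for (int j = 0; j < p; ++j) all_feats[j] = j;

  TreeParams par;
  par.max_depth = max_depth;
  par.lambda = lambda;
  par.min_child_weight = min_child_weight;
  par.colsample_bylevel = colsample_bylevel;
  par.min_gain = 1e-12;

  List trees(nrounds);
  NumericVector valid_rmse(has_val ? nrounds : 0);
  double best_score = std::numeric_limits<double>::infinity();
  int best_iter = 0, rounds_done = 0, since_best = 0;

  for (int it = 0; it < nrounds; ++it) {
    for (int r = 0; r < n; ++r) {
      const bool in = (subsample >= 1.0) || (unif(rng) < subsample);
      g[r] = in ? (pred[r] - y[r]) : 0.0;
      h[r] = in ? 1.0 : 0.0;
    }
    std::vector<int> feats = all_feats;
    if (colsample_bytree < 1.0) {
      int keep = std::max(1, (int)std::round(colsample_bytree * p));
      std::shuffle(feats.begin(), feats.end(), rng);
      feats.resize(keep);
      std::sort(feats.begin(), feats.end());
    }
    std::vector<Node> nodes = grow_tree(X, g, h, sorted_feat, feats, par, rng);
    NumericMatrix M = pack_tree(nodes, eta);
    trees[it] = M;
    ++rounds_done;
    for (int r = 0; r < n; ++r) pred[r] += tree_predict_row(M, X, r);
    if (has_val) {
      double sse = 0.0;
      for (int r = 0; r < nval; ++r) {
        predval[r] += tree_predict_row(M, Xval, r);
        const double e = predval[r] - yval[r];
        sse += e * e;
      }
      const double rmse = std::sqrt(sse / std::max(1, nval));
      valid_rmse[it] = rmse;
      if (rmse < best_score - 1e-12) {
        best_score = rmse;
        best_iter = it + 1;
        since_best = 0;
      } else if (++since_best >= early_stopping_rounds &&
                 early_stopping_rounds > 0) {
        break;
      }
    } else {
      best_iter = it + 1;
    }
  }

  double sse_train = 0.0;
  for (int r = 0; r < n; ++r) {
    const double e = pred[r] - y[r];
    sse_train += e * e;
  }

  List keep(rounds_done);
  for (int i = 0; i < rounds_done; ++i) keep[i] = trees[i];
  NumericVector vr(has_val ? rounds_done : 0);
  for (int i = 0; i < vr.size(); ++i) vr[i] = valid_rmse[i];

  return List::create(_["trees"] = keep,
                      _["base_score"] = base,
                      _["best_iter"] = best_iter,
                      _["n_rounds"] = rounds_done,
                      _["train_rmse"] = std::sqrt(sse_train / n),
                      _["valid_rmse"] = vr,
                      _["best_valid_rmse"] = has_val ? best_score : NA_REAL);
}

// [[Rcpp::export(name = ".cpp_boost_predict")]]
NumericVector cpp_boost_predict(List trees, double base_score,
                                NumericMatrix X, int ntree_limit) {
  const int n = X.nrow();
  const int T = (ntree_limit > 0 && ntree_limit < trees.size())
                  ? ntree_limit : trees.size();
  NumericVector out(n, base_score);
  for (int t = 0; t < T; ++t) {
    NumericMatrix M = trees[t];
    for (int r = 0; r < n; ++r) out[r] += tree_predict_row(M, X, r);
  }
  return out;
}

// Saabas path attribution: per row, per feature, the summed change in node
// value along the prediction path at splits on that feature, accumulated
// over the first `ntree_limit` trees. Node values are already on the
// shrunken (eta-scaled) prediction scale.
// [[Rcpp::export(name = ".cpp_path_attribution")]]
NumericMatrix cpp_path_attribution(List trees, NumericMatrix X,
                                   int ntree_limit) {
  const int n = X.nrow(), p = X.ncol();
  const int T = (ntree_limit > 0 && ntree_limit < trees.size())
                  ? ntree_limit : trees.size();
  NumericMatrix phi(n, p);
  for (int t = 0; t < T; ++t) {
    NumericMatrix M = trees[t];
    for (int r = 0; r < n; ++r) {
      int u = 0;
      while (M(u, 0) >= 0) {
        const int j = (int)M(u, 0);
        const int v = (X(r, j) < M(u, 1)) ? (int)M(u, 2) : (int)M(u, 3);
        phi(r, j) += M(v, 4) - M(u, 4);
        u = v;
      }
    }
  }
  return phi;
}

// Bagged random forest regression (bootstrap rows via integer count weights,
// per-tree column subsample, leaf = node mean). Used as the base learner of
// the iterative imputer.
// [[Rcpp::export(name = ".cpp_forest_fit")]]
List cpp_forest_fit(NumericMatrix X, NumericVector y,
                    int ntree, int max_depth, double min_node,
                    double colsample, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 1 || p < 1) stop("empty training matrix");
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);

  std::vector<SortedFeature> sorted_feat = presort(X);
  std::vector<int> all_feats(p);
  for (int j = 0; j < p; ++j) all_feats[j] = j;

  TreeParams par;
  par.max_depth = max_depth;
  par.lambda = 0.0;
  par.min_child_weight = min_node;
  par.colsample_bylevel = 1.0;
  par.min_gain = 1e-12;

  List trees(ntree);
  std::vector<double> g(n), h(n);
  for (int t = 0; t < ntree; ++t) {
    std::vector<double> cnt(n, 0.0);
    for (int i = 0; i < n; ++i) cnt[pick(rng)] += 1.0;
    for (int r = 0; r < n; ++r) {
      g[r] = -y[r] * cnt[r];  // base score 0 => leaf value = weighted mean y
      h[r] = cnt[r];
    }
    std::vector<int> feats = all_feats;
    if (colsample < 1.0 && p > 1) {
      int keep = std::max(1, (int)std::round(colsample * p));
      std::shuffle(feats.begin(), feats.end(), rng);
      feats.resize(keep);
      std::sort(feats.begin(), feats.end());
    }
    std::vector<Node> nodes = grow_tree(X, g, h, sorted_feat, feats, par, rng);
    trees[t] = pack_tree(nodes, 1.0);
  }
  return List::create(_["trees"] = trees, _["ntree"] = ntree);
}

// [[Rcpp::export(name = ".cpp_forest_predict")]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int T = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < T; ++t) {
    NumericMatrix M = trees[t];
    for (int r = 0; r < n; ++r) out[r] += tree_predict_row(M, X, r);
  }
  if (T > 0) for (int r = 0; r < n; ++r) out[r] /= T;
  return out;
}
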