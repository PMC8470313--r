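// Tree ensembles used by the screening pipeline: a binary random-forest
// classifier (Gini/CART, bootstrap + feature subsampling) and an isolation
// forest for multivariate outlier scoring. Both use a private mt19937 RNG so
// results are reproducible from an integer seed independently of R's RNG.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feat;  // -1 => leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> value;  // fraction of positive labels at the node
};

int grow_cart(const NumericMatrix &X, const IntegerVector &y,
              std::vector<int> &idx, int lo, int hi, int depth, int max_depth,
              int mtry, std::mt19937 &rng, Tree &t) {
  int node = static_cast<int>(t.feat.size());
  t.feat.push_back(-1);
  t.thr.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  int n = hi - lo, pos = 0;
  for (int i = lo; i < hi; ++i) pos += y[idx[i]];
  double frac = static_cast<double>(pos) / n;
  t.value.push_back(frac);
  if (n < 2 || pos == 0 || pos == n || (max_depth > 0 && depth >= max_depth))
    return node;

  int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    std::uniform_int_distribution<int> d(j, p - 1);
    std::swap(feats[j], feats[d(rng)]);
  }

  double parent_imp = frac * (1.0 - frac);
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<std::pair<double, int>> vals(n);
  for (int jj = 0; jj < m; ++jj) {
    int f = feats[jj];
    for (int i = 0; i < n; ++i)
      vals[i] = {X(idx[lo + i], f), y[idx[lo + i]]};
    std::sort(vals.begin(), vals.end());
    int lpos = 0;
    for (int i = 0; i < n - 1; ++i) {
      lpos += vals[i].second;
      if (!(vals[i + 1].first > vals[i].first)) continue;
      int ln = i + 1, rn = n - ln, rpos = pos - lpos;
      double fl = static_cast<double>(lpos) / ln;
      double fr = static_cast<double>(rpos) / rn;
      double imp = (ln * fl * (1.0 - fl) + rn * fr * (1.0 - fr)) / n;
      double gain = parent_imp - imp;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;

  t.feat[node] = best_f;
  t.thr[node] = best_thr;
  t.left[node] = grow_cart(X, y, idx, lo, mid, depth + 1, max_depth, mtry, rng, t);
  t.right[node] = grow_cart(X, y, idx, mid, hi, depth + 1, max_depth, mtry, rng, t);
  return node;
}

List tree_to_list(const Tree &t) {
  return List::create(Named("feat") = wrap(t.feat), Named("thr") = wrap(t.thr),
                      Named("left") = wrap(t.left),
                      Named("right") = wrap(t.right),
                      Named("value") = wrap(t.value));
}

double traverse(const IntegerVector &feat, const NumericVector &thr,
                const IntegerVector &left, const IntegerVector &right,
                const NumericVector &value, const NumericMatrix &X, int row) {
  int node = 0;
  while (feat[node] >= 0) {
    node = (X(row, feat[node]) <= thr[node]) ? left[node] : right[node];
  }
  return value[node];
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int max_depth,
                int mtry, int seed) {
  int n = X.nrow();
  std::mt19937 rng(static_cast<unsigned int>(seed));
  List forest(n_trees);
  std::uniform_int_distribution<int> boot(0, n - 1);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    Tree t;
    grow_cart(X, y, idx, 0, n, 0, max_depth, mtry, rng, t);
    forest[b] = tree_to_list(t);
  }
  return forest;
}

// Fraction of trees whose leaf majority votes the positive (outlier) class.
// [[Rcpp::export]]
NumericVector rf_vote_cpp(List forest, NumericMatrix X) {
  int n = X.nrow(), B = forest.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    List t = forest[b];
    IntegerVector feat = t["feat"], left = t["left"], right = t["right"];
    NumericVector thr = t["thr"], value = t["value"];
    for (int i = 0; i < n; ++i) {
      if (traverse(feat, thr, left, right, value, X, i) >= 0.5) out[i] += 1.0;
    }
  }
  return out / static_cast<double>(B);
}

namespace {

struct ITree {
  std::vector<int> feat;  // -1 => leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> adj;  // average-path-length adjustment for leaf size
};

double avg_path(double n) {
  if (n <= 1.0) return 0.0;
  const double euler = 0.5772156649015329;
  return 2.0 * (std::log(n - 1.0) + euler) - 2.0 * (n - 1.0) / n;
}

int grow_itree(const NumericMatrix &X, std::vector<int> &idx, int lo, int hi,
               int depth, int limit, std::mt19937 &rng, ITree &t) {
  int node = static_cast<int>(t.feat.size());
  t.feat.push_back(-1);
  t.thr.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  int n = hi - lo;
  t.adj.push_back(avg_path(static_cast<double>(n)));
  if (n <= 1 || depth >= limit) return node;

  int p = X.ncol();
  // pick a random feature with spread; give up after a few tries
  int f = -1;
  double mn = 0, mx = 0;
  std::uniform_int_distribution<int> df(0, p - 1);
  for (int tries = 0; tries < 8; ++tries) {
    int cand = df(rng);
    mn = mx = X(idx[lo], cand);
    for (int i = lo + 1; i < hi; ++i) {
      double v = X(idx[i], cand);
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    if (mx > mn) {
      f = cand;
      break;
    }
  }
  if (f < 0) return node;
  std::uniform_real_distribution<double> du(mn, mx);
  double thr = du(rng);

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], f) < thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;

  t.feat[node] = f;
  t.thr[node] = thr;
  t.left[node] = grow_itree(X, idx, lo, mid, depth + 1, limit, rng, t);
  t.right[node] = grow_itree(X, idx, mid, hi, depth + 1, limit, rng, t);
  return node;
}

}  // namespace

// Isolation-forest anomaly scores in (0, 1); larger = more anomalous.
// [[Rcpp::export]]
NumericVector iforest_scores_cpp(NumericMatrix X, int n_trees, int sample_size,
                                 int seed) {
  int n = X.nrow();
  int psi = std::min(sample_size, n);
  int limit = static_cast<int>(std::ceil(std::log2(std::max(psi, 2))));
  std::mt19937 rng(static_cast<unsigned int>(seed));
  NumericVector h(n);
  std::uniform_int_distribution<int> ds(0, n - 1);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(psi);
    for (int i = 0; i < psi; ++i) idx[i] = ds(rng);
    ITree t;
    grow_itree(X, idx, 0, psi, 0, limit, rng, t);
    for (int i = 0; i < n; ++i) {
      int node = 0, depth = 0;
      while (t.feat[node] >= 0) {
        node = (X(i, t.feat[node]) < t.thr[node]) ? t.left[node] : t.right[node];
        ++depth;
      }
      h[i] += depth + t.adj[node];
    }
  }
  double c = avg_path(static_cast<double>(psi));
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = std::pow(2.0, -(h[i] / n_trees) / c);
  return out;
}

// Accelerated projected-gradient (FISTA) solver for the one-class SVM dual:
// minimize 1/2 a'Ka subject to 0 <= a_i <= C, sum(a) = 1.

namespace {

void project_capped_simplex(std::vector<double> &a, const std::vector<double> &v,
                            double C) {
  double lo = v[0], hi = v[0];
  for (double x : v) {
    if (x < lo) lo = x;
    if (x > hi) hi = x;
  }
  lo -= C + 1.0;
  for (int it = 0; it < 64; ++it) {
    double mid = 0.5 * (lo + hi), s = 0.0;
    for (double x : v) {
      double z = x - mid;
      if (z > C) z = C;
      if (z > 0) s += z;
    }
    if (s > 1.0) lo = mid; else hi = mid;
  }
  double tau = 0.5 * (lo + hi);
  for (size_t i = 0; i < v.size(); ++i) {
    double z = v[i] - tau;
    if (z < 0) z = 0;
    if (z > C) z = C;
    a[i] = z;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector ocsvm_solve_cpp(NumericMatrix K, double C, int max_iter,
                              double tol) {
  int n = K.nrow();
  // Lipschitz constant: spectral norm of K by fixed-start power iteration
  std::vector<double> v(n, 1.0 / std::sqrt((double)n)), w(n);
  double L = 1e-8;
  for (int it = 0; it < 40; ++it) {
    double nv = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += K(i, j) * v[j];
      w[i] = s;
      nv += s * s;
    }
    nv = std::sqrt(nv);
    if (nv < 1e-300) break;
    double ray = 0.0;
    for (int i = 0; i < n; ++i) {
      ray += v[i] * w[i];
      v[i] = w[i] / nv;
    }
    L = std::max(L, ray);
  }
  L *= 1.05;

  std::vector<double> alpha(n), y(n, 1.0 / n), g(n), a_new(n), tmp(n);
  project_capped_simplex(alpha, y, C);
  y = alpha;
  double tk = 1.0;
  for (int it = 0; it < max_iter; ++it) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += K(i, j) * y[j];
      tmp[i] = y[i] - s / L;
    }
    project_capped_simplex(a_new, tmp, C);
    // adaptive restart (gradient scheme): reset momentum when the update
    // direction opposes the gradient at the extrapolated point
    double dot = 0.0;
    for (int i = 0; i < n; ++i) dot += (y[i] - tmp[i]) * (a_new[i] - alpha[i]);
    if (dot > 0.0) tk = 1.0;
    double t_new = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tk * tk));
    double delta = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = a_new[i] - alpha[i];
      if (std::fabs(d) > delta) delta = std::fabs(d);
      y[i] = a_new[i] + ((tk - 1.0) / t_new) * d;
      alpha[i] = a_new[i];
    }
    tk = t_new;
    if (delta < tol) break;
  }
  return wrap(alpha);
}
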