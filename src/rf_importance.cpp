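// Random-forest Gini importance for the shadow-feature selection loop.
// Classification forest: bootstrap samples, mtry random candidate features
// per node, best Gini split, mean-decrease-in-impurity accumulated per
// feature. Only importances are needed downstream, so the forest keeps no
// tree structure and does no prediction. Uses R's RNG so results are
// reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct NodeJob {
  int start, end;  // range in the index buffer
};

// uniform integer in [0, n)
inline int rand_int(int n) {
  int v = static_cast<int>(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

}  // namespace

// [[Rcpp::export(name = ".rf_gini_importance")]]
NumericVector rf_gini_importance(NumericMatrix x, IntegerVector y,
                                 int ntree = 500, int mtry = 0,
                                 int min_node = 5) {
  const int n = x.nrow(), p = x.ncol();
  if (y.size() != n) stop("length(y) != nrow(x)");
  int n_class = 0;
  for (int i = 0; i < n; ++i) {
    if (y[i] < 0) stop("class labels must be 0-based non-negative");
    n_class = std::max(n_class, y[i] + 1);
  }
  if (n_class < 2) stop("need at least two classes");
  if (mtry <= 0) mtry = std::max(1, (int)std::floor(std::sqrt((double)p)));
  mtry = std::min(mtry, p);

  const double *xp = REAL(x);  // column-major
  NumericVector importance(p);
  std::vector<int> idx(n), feat(p);
  std::vector<std::pair<double, int> > vals(n);  // (feature value, class)
  std::vector<int> left_counts(n_class), node_counts(n_class);

  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = rand_int(n);  // bootstrap

    std::vector<NodeJob> stack;
    stack.push_back(NodeJob{0, n});
    while (!stack.empty()) {
      NodeJob job = stack.back();
      stack.pop_back();
      const int m = job.end - job.start;
      if (m < 2 * min_node) continue;

      std::fill(node_counts.begin(), node_counts.end(), 0);
      for (int i = job.start; i < job.end; ++i) ++node_counts[y[idx[i]]];
      double ssq_node = 0.0;
      for (int k = 0; k < n_class; ++k)
        ssq_node += (double)node_counts[k] * node_counts[k];
      const double imp_parent = 1.0 - ssq_node / ((double)m * m);
      if (imp_parent <= 0.0) continue;  // pure node

      // sample mtry candidate features without replacement
      for (int j = 0; j < p; ++j) feat[j] = j;
      int best_f = -1;
      double best_gain = 1e-12, best_thr = 0.0;
      for (int c = 0; c < mtry; ++c) {
        int pick = c + rand_int(p - c);
        std::swap(feat[c], feat[pick]);
        const int f = feat[c];
        const double *col = xp + (size_t)f * n;

        for (int i = 0; i < m; ++i) {
          const int s = idx[job.start + i];
          vals[i] = std::make_pair(col[s], y[s]);
        }
        std::sort(vals.begin(), vals.begin() + m);
        if (vals[0].first == vals[m - 1].first) continue;  // constant

        // incremental class counts and sums of squared counts on both sides
        std::fill(left_counts.begin(), left_counts.end(), 0);
        double ssq_l = 0.0, ssq_r = ssq_node;
        int nl = 0;
        for (int i = 0; i < m - 1; ++i) {
          const int k = vals[i].second;
          ssq_l += 2.0 * left_counts[k] + 1.0;
          const int rk = node_counts[k] - left_counts[k];
          ssq_r -= 2.0 * rk - 1.0;
          ++left_counts[k];
          ++nl;
          if (vals[i].first == vals[i + 1].first) continue;
          if (nl < min_node || m - nl < min_node) continue;
          const int nr = m - nl;
          const double impl = 1.0 - ssq_l / ((double)nl * nl);
          const double impr = 1.0 - ssq_r / ((double)nr * nr);
          const double gain = imp_parent -
            ((double)nl / m) * impl - ((double)nr / m) * impr;
          if (gain > best_gain) {
            best_gain = gain;
            best_f = f;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      }
      if (best_f < 0) continue;

      importance[best_f] += ((double)m / n) * best_gain;

      // partition index range around the chosen split
      const double *col = xp + (size_t)best_f * n;
      int lo = job.start, hi = job.end - 1;
      while (lo <= hi) {
        if (col[idx[lo]] <= best_thr) {
          ++lo;
        } else {
          std::swap(idx[lo], idx[hi]);
          --hi;
        }
      }
      if (lo > job.start && lo < job.end) {
        stack.push_back(NodeJob{job.start, lo});
        stack.push_back(NodeJob{lo, job.end});
      }
    }
  }
  for (int j = 0; j < p; ++j) importance[j] /= ntree;
  return importance;
}

// OOB permutation importance with per-tree Z normalization (classic
// random-forest "mean decrease accuracy, scaled"). Trees are stored so each
// feature used by a tree can be permuted among that tree's out-of-bag
// samples; the importance is mean(acc_drop) / se(acc_drop) over trees.
// This is the default importance for the shadow-feature loop: out-of-bag
// evaluation keeps noise features exchangeable with their shadows, which
// in-bag Gini gain is not.

// [[Rcpp::export(name = ".rf_perm_importance")]]
NumericVector rf_perm_importance(NumericMatrix x, IntegerVector y,
                                 int ntree = 500, int mtry = 0,
                                 int min_node = 5) {
  const int n = x.nrow(), p = x.ncol();
  if (y.size() != n) stop("length(y) != nrow(x)");
  int n_class = 0;
  for (int i = 0; i < n; ++i) {
    if (y[i] < 0) stop("class labels must be 0-based non-negative");
    n_class = std::max(n_class, y[i] + 1);
  }
  if (n_class < 2) stop("need at least two classes");
  if (mtry <= 0) mtry = std::max(1, (int)std::floor(std::sqrt((double)p)));
  mtry = std::min(mtry, p);

  const double *xp = REAL(x);
  std::vector<double> imp_sum(p, 0.0), imp_ssq(p, 0.0);
  std::vector<int> idx(n), inbag(n), feat(p);
  std::vector<std::pair<double, int> > vals(n);
  std::vector<int> left_counts(n_class), node_counts(n_class);

  // flat tree storage, rebuilt per tree
  std::vector<int> nd_feat, nd_left, nd_right, nd_pred;
  std::vector<double> nd_thr;

  struct Job { int start, end, parent; bool is_left; };

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      int s = rand_int(n);
      idx[i] = s;
      ++inbag[s];
    }
    nd_feat.clear(); nd_left.clear(); nd_right.clear();
    nd_pred.clear(); nd_thr.clear();

    std::vector<Job> stack;
    stack.push_back(Job{0, n, -1, false});
    while (!stack.empty()) {
      Job job = stack.back();
      stack.pop_back();
      const int m = job.end - job.start;
      const int node_id = (int)nd_feat.size();
      if (job.parent >= 0) {
        if (job.is_left) nd_left[job.parent] = node_id;
        else nd_right[job.parent] = node_id;
      }
      std::fill(node_counts.begin(), node_counts.end(), 0);
      for (int i = job.start; i < job.end; ++i) ++node_counts[y[idx[i]]];
      int pred = 0;
      for (int k = 1; k < n_class; ++k)
        if (node_counts[k] > node_counts[pred]) pred = k;
      nd_feat.push_back(-1); nd_left.push_back(-1); nd_right.push_back(-1);
      nd_pred.push_back(pred); nd_thr.push_back(0.0);

      if (m < 2 * min_node) continue;
      double ssq_node = 0.0;
      for (int k = 0; k < n_class; ++k)
        ssq_node += (double)node_counts[k] * node_counts[k];
      const double imp_parent = 1.0 - ssq_node / ((double)m * m);
      if (imp_parent <= 0.0) continue;

      for (int j = 0; j < p; ++j) feat[j] = j;
      int best_f = -1;
      double best_gain = 1e-12, best_thr = 0.0;
      for (int c = 0; c < mtry; ++c) {
        int pick = c + rand_int(p - c);
        std::swap(feat[c], feat[pick]);
        const int f = feat[c];
        const double *col = xp + (size_t)f * n;
        for (int i = 0; i < m; ++i) {
          const int s = idx[job.start + i];
          vals[i] = std::make_pair(col[s], y[s]);
        }
        std::sort(vals.begin(), vals.begin() + m);
        if (vals[0].first == vals[m - 1].first) continue;
        std::fill(left_counts.begin(), left_counts.end(), 0);
        double ssq_l = 0.0, ssq_r = ssq_node;
        int nl = 0;
        for (int i = 0; i < m - 1; ++i) {
          const int k = vals[i].second;
          ssq_l += 2.0 * left_counts[k] + 1.0;
          const int rk = node_counts[k] - left_counts[k];
          ssq_r -= 2.0 * rk - 1.0;
          ++left_counts[k];
          ++nl;
          if (vals[i].first == vals[i + 1].first) continue;
          if (nl < min_node || m - nl < min_node) continue;
          const int nr = m - nl;
          const double impl = 1.0 - ssq_l / ((double)nl * nl);
          const double impr = 1.0 - ssq_r / ((double)nr * nr);
          const double gain = imp_parent -
            ((double)nl / m) * impl - ((double)nr / m) * impr;
          if (gain > best_gain) {
            best_gain = gain;
            best_f = f;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      }
      if (best_f < 0) continue;

      const double *col = xp + (size_t)best_f * n;
      int lo = job.start, hi = job.end - 1;
      while (lo <= hi) {
        if (col[idx[lo]] <= best_thr) ++lo;
        else { std::swap(idx[lo], idx[hi]); --hi; }
      }
      if (lo > job.start && lo < job.end) {
        nd_feat[node_id] = best_f;
        nd_thr[node_id] = best_thr;
        stack.push_back(Job{job.start, lo, node_id, true});
        stack.push_back(Job{lo, job.end, node_id, false});
      }
    }

    // OOB evaluation
    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (inbag[i] == 0) oob.push_back(i);
    const int n_oob = (int)oob.size();
    if (n_oob < 2) continue;

    std::vector<int> used;
    for (size_t u = 0; u < nd_feat.size(); ++u)
      if (nd_feat[u] >= 0) used.push_back(nd_feat[u]);
    std::sort(used.begin(), used.end());
    used.erase(std::unique(used.begin(), used.end()), used.end());
    if (used.empty()) continue;

    // predict sample s, overriding feature pf with value pv (pf = -1: none)
    struct Pred {
      const std::vector<int> &nf, &nl, &nr, &np;
      const std::vector<double> &nt;
      const double *xp; int n;
      int operator()(int s, int pf, double pv) const {
        int node = 0;
        while (nf[node] >= 0) {
          double v = (nf[node] == pf) ? pv : xp[(size_t)nf[node] * n + s];
          node = (v <= nt[node]) ? nl[node] : nr[node];
        }
        return np[node];
      }
    } predict{nd_feat, nd_left, nd_right, nd_pred, nd_thr, xp, n};

    int correct = 0;
    for (int i = 0; i < n_oob; ++i)
      if (predict(oob[i], -1, 0.0) == y[oob[i]]) ++correct;
    const double acc0 = (double)correct / n_oob;

    std::vector<int> perm(oob);
    for (size_t uf = 0; uf < used.size(); ++uf) {
      const int f = used[uf];
      for (int i = n_oob - 1; i > 0; --i)
        std::swap(perm[i], perm[rand_int(i + 1)]);
      const double *col = xp + (size_t)f * n;
      int corr = 0;
      for (int i = 0; i < n_oob; ++i)
        if (predict(oob[i], f, col[perm[i]]) == y[oob[i]]) ++corr;
      const double drop = acc0 - (double)corr / n_oob;
      imp_sum[f] += drop;
      imp_ssq[f] += drop * drop;
    }
  }

  NumericVector importance(p);
  for (int f = 0; f < p; ++f) {
    const double mean = imp_sum[f] / ntree;
    const double var = imp_ssq[f] / ntree - mean * mean;
    const double se = std::sqrt(std::max(var, 0.0) / ntree);
    importance[f] = (se > 0.0) ? mean / se : mean;
  }
  return importance;
}
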