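#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Monte Carlo feature selection engine.
//
// Grows binary classification trees on random feature subsets and random
// stratified train/test splits of a discretized decision table (three-state
// categorical features coded 0/1/2). Each tree contributes to the relative
// importance (RI) of every feature g that splits one of its nodes:
//   RI_g += wAcc(tree)^u * sum_nodes [ IG(node) * n(node)/n(root) ]^v
// where wAcc is the mean per-class sensitivity on the held-out split and IG
// the information gain (log2) of the node split. Splits partition the state
// set as one-state-vs-rest; trees are grown to purity with a minimum leaf
// size; ties on IG go to the lowest feature index, then lowest state.

namespace {

struct TreeNode {
    int feat = -1;     // splitting feature (-1 => leaf)
    int part = -1;     // state sent to the left child
    int left = -1, right = -1;
    int pred = -1;     // majority training class (leaf prediction)
};

inline double entropy(const std::vector<int>& cnt, int n) {
    if (n == 0) return 0.0;
    double h = 0.0;
    for (int c : cnt) {
        if (c > 0) {
            double p = (double)c / n;
            h -= p * std::log2(p);
        }
    }
    return h;
}

// Fisher-Yates partial shuffle using R's RNG (first k entries random).
inline void partial_shuffle(std::vector<int>& v, int k) {
    int n = (int)v.size();
    for (int i = 0; i < k && i < n - 1; ++i) {
        int j = i + (int)(unif_rand() * (n - i));
        if (j >= n) j = n - 1;
        std::swap(v[i], v[j]);
    }
}

struct SplitRec { int feat; double ig; double frac; };

class TreeBuilder {
public:
    TreeBuilder(const IntegerMatrix& states, const IntegerVector& cls,
                int n_classes, int min_leaf)
        : st_(states), cls_(cls), C_(n_classes), min_leaf_(min_leaf) {}

    // Grow on the training indices using the given (sorted) feature subset.
    void grow(const std::vector<int>& train, const std::vector<int>& feats) {
        nodes_.clear();
        splits_.clear();
        n_root_ = (int)train.size();
        build(train, feats);
    }

    int predict(int sample) const {
        int node = 0;
        while (nodes_[node].feat >= 0) {
            int v = st_(sample, nodes_[node].feat);
            node = (v == nodes_[node].part) ? nodes_[node].left
                                            : nodes_[node].right;
        }
        return nodes_[node].pred;
    }

    const std::vector<SplitRec>& splits() const { return splits_; }

private:
    const IntegerMatrix& st_;
    const IntegerVector& cls_;
    int C_, min_leaf_, n_root_ = 0;
    std::vector<TreeNode> nodes_;
    std::vector<SplitRec> splits_;

    int build(const std::vector<int>& idx, const std::vector<int>& feats) {
        int me = (int)nodes_.size();
        nodes_.push_back(TreeNode());
        int n = (int)idx.size();
        std::vector<int> cnt(C_, 0);
        for (int i : idx) cnt[cls_[i]]++;
        int best_c = 0;
        for (int c = 1; c < C_; ++c) if (cnt[c] > cnt[best_c]) best_c = c;
        nodes_[me].pred = best_c;
        double h = entropy(cnt, n);
        if (h <= 0.0 || n < 2 * min_leaf_) return me;

        int bf = -1, bp = -1;
        double big = 0.0;
        for (int f : feats) {
            int vc[3] = {0, 0, 0};
            std::vector<int> vcc(3 * C_, 0);
            for (int i : idx) {
                int v = st_(i, f);
                vc[v]++;
                vcc[v * C_ + cls_[i]]++;
            }
            for (int v = 0; v < 3; ++v) {
                int nL = vc[v], nR = n - nL;
                if (nL < min_leaf_ || nR < min_leaf_) continue;
                std::vector<int> cl(vcc.begin() + v * C_,
                                    vcc.begin() + (v + 1) * C_);
                std::vector<int> cr(C_);
                for (int c = 0; c < C_; ++c) cr[c] = cnt[c] - cl[c];
                double ig = h - ((double)nL / n) * entropy(cl, nL)
                              - ((double)nR / n) * entropy(cr, nR);
                if (ig > big + 1e-12) { big = ig; bf = f; bp = v; }
            }
        }
        if (bf < 0 || big <= 1e-12) return me;

        splits_.push_back({bf, big, (double)n / n_root_});
        std::vector<int> li, ri;
        for (int i : idx) {
            if (st_(i, bf) == bp) li.push_back(i); else ri.push_back(i);
        }
        nodes_[me].feat = bf;
        nodes_[me].part = bp;
        int l = build(li, feats);
        int r = build(ri, feats);
        nodes_[me].left = l;
        nodes_[me].right = r;
        return me;
    }
};

} // namespace

// [[Rcpp::export]]
List mcfs_engine_cpp(IntegerMatrix states, IntegerVector cls, int n_classes,
                     int n_subsets, int subset_size, int n_splits,
                     double train_frac, double u, double v, int min_leaf,
                     bool record) {
    const int n = states.nrow(), d = states.ncol();
    if (cls.size() != n) stop("class labels must match the sample count");
    if (subset_size < 2 || subset_size > d)
        stop("feature subset size must lie in [2, n_features]");

    std::vector<std::vector<int>> by_class(n_classes);
    for (int i = 0; i < n; ++i) {
        if (cls[i] < 0 || cls[i] >= n_classes) stop("bad class code");
        by_class[cls[i]].push_back(i);
    }
    for (int c = 0; c < n_classes; ++c)
        if ((int)by_class[c].size() < 2)
            stop("every class needs >= 2 samples for a stratified split");

    NumericVector ri(d);
    List trees(record ? n_subsets * n_splits : 0);
    std::vector<int> pool(d);
    for (int f = 0; f < d; ++f) pool[f] = f;
    TreeBuilder tb(states, cls, n_classes, min_leaf);
    int tree_idx = 0;

    for (int s = 0; s < n_subsets; ++s) {
        partial_shuffle(pool, subset_size);
        std::vector<int> feats(pool.begin(), pool.begin() + subset_size);
        std::sort(feats.begin(), feats.end());

        for (int t = 0; t < n_splits; ++t) {
            std::vector<int> train, test;
            for (int c = 0; c < n_classes; ++c) {
                std::vector<int> mem = by_class[c];
                int nc = (int)mem.size();
                int ntr = (int)std::lround(train_frac * nc);
                if (ntr < 1) ntr = 1;
                if (ntr > nc - 1) ntr = nc - 1;
                partial_shuffle(mem, nc - 1);
                train.insert(train.end(), mem.begin(), mem.begin() + ntr);
                test.insert(test.end(), mem.begin() + ntr, mem.end());
            }
            tb.grow(train, feats);

            std::vector<int> correct(n_classes, 0), total(n_classes, 0);
            for (int i : test) {
                total[cls[i]]++;
                if (tb.predict(i) == cls[i]) correct[cls[i]]++;
            }
            double wacc = 0.0;
            int npresent = 0;
            for (int c = 0; c < n_classes; ++c) {
                if (total[c] > 0) {
                    wacc += (double)correct[c] / total[c];
                    npresent++;
                }
            }
            wacc /= npresent;

            const std::vector<SplitRec>& sp = tb.splits();
            double w = std::pow(wacc, u);
            std::vector<double> contrib(d, 0.0);
            for (const SplitRec& r : sp)
                contrib[r.feat] += std::pow(r.ig * r.frac, v);
            for (int f = 0; f < d; ++f)
                if (contrib[f] > 0.0) ri[f] += w * contrib[f];

            if (record) {
                int ns = (int)sp.size();
                IntegerVector rf(ns);
                NumericVector rig(ns), rfr(ns);
                for (int k = 0; k < ns; ++k) {
                    rf[k] = sp[k].feat + 1;  // 1-based for R
                    rig[k] = sp[k].ig;
                    rfr[k] = sp[k].frac;
                }
                trees[tree_idx] = List::create(
                    Named("feature") = rf, Named("ig") = rig,
                    Named("frac") = rfr, Named("wacc") = wacc);
            }
            tree_idx++;
        }
    }
    return List::create(Named("ri") = ri, Named("trees") = trees);
}
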