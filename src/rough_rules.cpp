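#include <Rcpp.h>
#include <vector>
#include <string>
#include <map>
#include <set>
#include <algorithm>
using namespace Rcpp;

// Object-related reduct computation for rough-set rule induction.
//
// For each object, the discernibility family holds, per other-class object,
// the attribute set (bitmask) on which the two differ; empty masks
// (indiscernible pairs, i.e. contradictions) are skipped. Reducts are the
// minimal hitting sets of that family. "exhaustive" enumerates all of them
// (branch over the elements of the first uncovered set, excluding elements
// tried in earlier sibling branches, then a witness check keeps exactly the
// minimal transversals); "johnson" keeps one greedy set-cover reduct with
// ties to the lowest attribute index, pruned of redundant attributes.
// Limited to 64 attributes (bitmask width); callers fall back to the R
// implementation beyond that.

namespace {

typedef unsigned long long u64;

inline int popcount(u64 x) { return __builtin_popcountll(x); }

void mhs_rec(const std::vector<u64>& fam, u64 partial, u64 excluded,
             std::vector<u64>& out, int max_out) {
    if (fam.empty()) {
        out.push_back(partial);
        if ((int)out.size() > max_out)
            stop("reduct enumeration exceeded %d sets for one object; "
                 "use method = \"johnson\"", max_out);
        return;
    }
    u64 S = fam[0] & ~excluded;
    u64 before = 0;
    while (S) {
        u64 bit = S & (~S + 1);   // lowest set bit
        S ^= bit;
        std::vector<u64> fam2;
        fam2.reserve(fam.size());
        for (u64 m : fam)
            if (!(m & bit)) fam2.push_back(m);
        mhs_rec(fam2, partial | bit, excluded | before, out, max_out);
        before |= bit;
    }
}

std::vector<u64> minimal_hitting_sets(const std::vector<u64>& fam,
                                      int max_out) {
    std::vector<u64> out;
    mhs_rec(fam, 0ULL, 0ULL, out, max_out);
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
    std::vector<u64> keep;
    for (u64 h : out) {
        bool minimal = true;
        u64 rest = h;
        while (rest && minimal) {
            u64 bit = rest & (~rest + 1);
            rest ^= bit;
            bool witness = false;
            for (u64 m : fam)
                if ((m & h) == bit) { witness = true; break; }
            if (!witness) minimal = false;
        }
        if (minimal) keep.push_back(h);
    }
    return keep;
}

u64 johnson_reduct(const std::vector<u64>& fam, int d) {
    std::vector<u64> rem = fam;
    u64 chosen = 0;
    std::vector<int> order;
    while (!rem.empty()) {
        int best = -1, best_cnt = -1;
        for (int a = 0; a < d; ++a) {
            u64 bit = 1ULL << a;
            if (chosen & bit) continue;
            int cnt = 0;
            for (u64 m : rem) if (m & bit) cnt++;
            if (cnt > best_cnt) { best_cnt = cnt; best = a; }
        }
        u64 bit = 1ULL << best;
        chosen |= bit;
        order.push_back(best);
        std::vector<u64> nxt;
        for (u64 m : rem) if (!(m & bit)) nxt.push_back(m);
        rem = nxt;
    }
    // drop attributes made redundant by later picks
    for (int i = (int)order.size() - 1; i >= 0; --i) {
        u64 bit = 1ULL << order[i];
        u64 cand = chosen & ~bit;
        if (!cand) continue;
        bool covers = true;
        for (u64 m : fam)
            if (!(m & cand)) { covers = false; break; }
        if (covers) chosen = cand;
    }
    return chosen;
}

} // namespace

// [[Rcpp::export]]
List induce_reducts_cpp(IntegerMatrix st, IntegerVector cls, bool exhaustive,
                        int max_reducts) {
    const int n = st.nrow(), d = st.ncol();
    if (d > 64) stop("bitmask reducts support at most 64 attributes");

    // row patterns for dedup of identical (pattern, class) objects
    std::vector<std::string> pat(n);
    for (int i = 0; i < n; ++i) {
        std::string s(d + 1, '0');
        for (int j = 0; j < d; ++j) s[j] = (char)('0' + st(i, j));
        s[d] = (char)('A' + cls[i]);
        pat[i] = s;
    }
    std::set<std::string> seen;
    std::vector<int> objects;
    std::vector<std::vector<u64>> reducts;

    for (int o = 0; o < n; ++o) {
        if (!seen.insert(pat[o]).second) continue;
        std::vector<u64> fam;
        for (int i = 0; i < n; ++i) {
            if (cls[i] == cls[o]) continue;
            u64 m = 0;
            for (int j = 0; j < d; ++j)
                if (st(i, j) != st(o, j)) m |= (1ULL << j);
            if (m) fam.push_back(m);
        }
        std::vector<u64> red;
        if (fam.empty()) {
            for (int j = 0; j < d; ++j) red.push_back(1ULL << j);
        } else {
            // minimize the family: drop supersets
            std::sort(fam.begin(), fam.end(),
                      [](u64 a, u64 b) { return popcount(a) < popcount(b); });
            std::vector<u64> minfam;
            for (u64 m : fam) {
                bool sup = false;
                for (u64 k : minfam)
                    if ((m & k) == k) { sup = true; break; }
                if (!sup) minfam.push_back(m);
            }
            red = exhaustive ? minimal_hitting_sets(minfam, max_reducts)
                             : std::vector<u64>{johnson_reduct(minfam, d)};
        }
        objects.push_back(o + 1);
        reducts.push_back(red);
    }

    List out(objects.size());
    for (size_t i = 0; i < objects.size(); ++i) {
        List rl(reducts[i].size());
        for (size_t k = 0; k < reducts[i].size(); ++k) {
            u64 m = reducts[i][k];
            std::vector<int> attrs;
            for (int j = 0; j < d; ++j)
                if (m & (1ULL << j)) attrs.push_back(j + 1);
            rl[k] = wrap(attrs);
        }
        out[i] = rl;
    }
    return List::create(Named("objects") = wrap(objects),
                        Named("reducts") = out);
}

// Evaluate rules against a table: support (matching samples) and the number
// of matching samples inside each rule's decision class.
// [[Rcpp::export]]
List evaluate_rules_cpp(IntegerMatrix st, IntegerVector cls,
                        List rule_attrs, List rule_states,
                        IntegerVector rule_dec) {
    const int n = st.nrow();
    const int R = rule_attrs.size();
    IntegerVector support(R), inclass(R);
    for (int r = 0; r < R; ++r) {
        IntegerVector a = rule_attrs[r];
        IntegerVector s = rule_states[r];
        const int L = a.size();
        int sup = 0, k = 0;
        for (int i = 0; i < n; ++i) {
            bool match = true;
            for (int j = 0; j < L; ++j) {
                if (st(i, a[j] - 1) != s[j]) { match = false; break; }
            }
            if (match) {
                sup++;
                if (cls[i] == rule_dec[r]) k++;
            }
        }
        support[r] = sup;
        inclass[r] = k;
    }
    return List::create(Named("support") = support,
                        Named("inclass") = inclass);
}

// Accumulate support*accuracy votes per sample and class.
// [[Rcpp::export]]
NumericMatrix vote_rules_cpp(IntegerMatrix st, int n_classes,
                             List rule_attrs, List rule_states,
                             IntegerVector rule_dec, NumericVector weight) {
    const int n = st.nrow();
    const int R = rule_attrs.size();
    NumericMatrix votes(n, n_classes);
    for (int r = 0; r < R; ++r) {
        IntegerVector a = rule_attrs[r];
        IntegerVector s = rule_states[r];
        const int L = a.size();
        for (int i = 0; i < n; ++i) {
            bool match = true;
            for (int j = 0; j < L; ++j) {
                if (st(i, a[j] - 1) != s[j]) { match = false; break; }
            }
            if (match) votes(i, rule_dec[r]) += weight[r];
        }
    }
    return votes;
}
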