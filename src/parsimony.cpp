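#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Binary-character parsimony on rooted binary trees.
//
// Node ids are 1-based: tips are 1..ntip (tip i holds column i of the state
// matrix), internal nodes have ids > ntip. lch[v] == 0 marks a tip. The root
// carries an implicit all-ancestral parent: under Wagner scoring an extra
// step is charged when state 0 cannot be assigned to the root; Camin-Sokal
// fixes the root lineage to 0 by construction.
//
// States are bitmasks per (pattern, tip): 1 = ancestral(0), 2 = derived(1).

struct TreeArrays {
    const int* lch;  // [0] unused, index by node id
    const int* rch;
    int ntip;
};

// Fitch downpass: fills `set` (length npat) with the preliminary state set of
// `v`, adding weighted change counts to `changes`.
static void fitch_down(int v, const TreeArrays& t, const IntegerMatrix& states,
                       const NumericVector& w, std::vector<int>& set,
                       double& changes) {
    const int npat = states.nrow();
    if (t.lch[v] == 0) {
        for (int p = 0; p < npat; ++p) set[p] = states(p, v - 1);
        return;
    }
    std::vector<int> a(npat), b(npat);
    fitch_down(t.lch[v], t, states, w, a, changes);
    fitch_down(t.rch[v], t, states, w, b, changes);
    for (int p = 0; p < npat; ++p) {
        int x = a[p] & b[p];
        if (x == 0) {
            x = a[p] | b[p];
            changes += w[p];
        }
        set[p] = x;
    }
}

// Camin-Sokal: a gain is charged at every maximal all-derived subtree
// (reversals forbidden, root lineage fixed ancestral). Fills `all1`.
static void cs_down(int v, const TreeArrays& t, const IntegerMatrix& states,
                    const NumericVector& w, std::vector<char>& all1,
                    double& gains) {
    const int npat = states.nrow();
    if (t.lch[v] == 0) {
        for (int p = 0; p < npat; ++p) all1[p] = (states(p, v - 1) == 2);
        return;
    }
    std::vector<char> a(npat), b(npat);
    cs_down(t.lch[v], t, states, w, a, gains);
    cs_down(t.rch[v], t, states, w, b, gains);
    for (int p = 0; p < npat; ++p) {
        all1[p] = (a[p] && b[p]);
        if (a[p] && !all1[p]) gains += w[p];
        if (b[p] && !all1[p]) gains += w[p];
    }
}

static double score_tree(const TreeArrays& t, int root,
                         const IntegerMatrix& states, const NumericVector& w,
                         int model /*0 wagner, 1 camin-sokal*/,
                         bool root_zero) {
    const int npat = states.nrow();
    double total = 0.0;
    if (model == 0) {
        std::vector<int> set(npat);
        fitch_down(root, t, states, w, set, total);
        if (root_zero) {
            for (int p = 0; p < npat; ++p)
                if (!(set[p] & 1)) total += w[p];
        }
    } else {
        std::vector<char> all1(npat);
        cs_down(root, t, states, w, all1, total);
        for (int p = 0; p < npat; ++p)
            if (all1[p]) total += w[p];  // gain on the root stem
    }
    return total;
}

// [[Rcpp::export]]
double score_tree_cpp(IntegerVector lch, IntegerVector rch, int root,
                      IntegerMatrix states, NumericVector weights,
                      int model, bool root_zero) {
    // R passes plain vectors whose element i holds node i's child; shift to
    // the 1-based node indexing used internally
    const int n = lch.size();
    std::vector<int> L(n + 1, 0), R(n + 1, 0);
    for (int i = 0; i < n; ++i) { L[i + 1] = lch[i]; R[i + 1] = rch[i]; }
    TreeArrays t{L.data(), R.data(), states.ncol()};
    return score_tree(t, root, states, weights, model, root_zero);
}

// ---------------------------------------------------------------------------
// Exhaustive (branch-and-bound) enumeration of rooted binary topologies.
// Tips are inserted in id order; inserting tip k above any current node
// (including above the root) generates each rooted topology exactly once.
// Partial-tree length is a lower bound on any completion, so partial trees
// longer than the incumbent are pruned; ties are always kept.

struct EnumCtx {
    int ntip, npat, model, cap;
    const IntegerMatrix* states;
    const NumericVector* weights;
    std::vector<int> L, R, par;
    std::vector<int> active;
    int root, next_internal;
    double best;
    long long n_opt;
    std::vector<std::string> newicks;
    const CharacterVector* labels;
};

static double score_ctx(EnumCtx& c) {
    TreeArrays t{c.L.data(), c.R.data(), c.ntip};
    return score_tree(t, c.root, *c.states, *c.weights, c.model, true);
}

static void build_newick(const EnumCtx& c, int v, std::string& out) {
    if (c.L[v] == 0) {
        out += Rcpp::as<std::string>((*c.labels)[v - 1]);
        return;
    }
    out += '(';
    build_newick(c, c.L[v], out);
    out += ',';
    build_newick(c, c.R[v], out);
    out += ')';
}

static void enum_rec(EnumCtx& c, int k) {
    if (k > c.ntip) {
        double s = score_ctx(c);
        if (s < c.best - 1e-9) {
            c.best = s;
            c.n_opt = 0;
            c.newicks.clear();
        }
        if (s <= c.best + 1e-9) {
            c.n_opt += 1;
            if ((int)c.newicks.size() < c.cap) {
                std::string nw;
                build_newick(c, c.root, nw);
                nw += ';';
                c.newicks.push_back(nw);
            }
        }
        return;
    }
    if (c.best < R_PosInf) {
        double s = score_ctx(c);
        if (s > c.best + 1e-9) return;  // bound: length can only grow
    }
    std::vector<int> positions(c.active);  // snapshot before mutation
    for (int v : positions) {
        int m = c.next_internal++;
        int pv = c.par[v];
        if (pv) {
            if (c.L[pv] == v) c.L[pv] = m; else c.R[pv] = m;
        } else {
            c.root = m;
        }
        c.par[m] = pv;
        c.L[m] = v; c.R[m] = k;
        c.par[v] = m; c.par[k] = m;
        c.active.push_back(m);
        c.active.push_back(k);

        enum_rec(c, k + 1);

        c.active.pop_back();
        c.active.pop_back();
        if (pv) {
            if (c.L[pv] == m) c.L[pv] = v; else c.R[pv] = v;
        } else {
            c.root = v;
        }
        c.par[v] = pv; c.par[k] = 0;
        c.L[m] = 0; c.R[m] = 0; c.par[m] = 0;
        c.next_internal--;
    }
}

// [[Rcpp::export]]
List exhaustive_cpp(IntegerMatrix states, NumericVector weights,
                    CharacterVector labels, int model, int cap) {
    const int ntip = states.ncol();
    if (ntip < 2) stop("need at least 2 taxa");
    EnumCtx c;
    c.ntip = ntip;
    c.npat = states.nrow();
    c.model = model;
    c.cap = cap;
    c.states = &states;
    c.weights = &weights;
    c.labels = &labels;
    const int nmax = 2 * ntip;  // 1..2*ntip-1 used
    c.L.assign(nmax + 1, 0);
    c.R.assign(nmax + 1, 0);
    c.par.assign(nmax + 1, 0);
    c.best = R_PosInf;
    c.n_opt = 0;
    // initial tree: root joins tips 1 and 2
    c.root = ntip + 1;
    c.next_internal = ntip + 2;
    c.L[c.root] = 1; c.R[c.root] = 2;
    c.par[1] = c.root; c.par[2] = c.root;
    c.active = {1, 2, c.root};

    enum_rec(c, 3);

    return List::create(_["length"] = c.best,
                        _["newick"] = wrap(c.newicks),
                        _["n_opt"] = (double)c.n_opt);
}
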