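#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Global alignment of ordered forests (tree alignment in the sense of
// Jiang, Wang & Zhang), specialised to RNA structure forests whose nodes
// are PAIR (internal, carries the two paired residues) or UNPAIRED (leaf,
// one residue). Forests may be profiles: every node carries one entry per
// aligned row (residue(s) or gap), and scores are sum-of-pairs over the
// rows of the two profiles, which makes progressive multiple structure
// alignment a sequence of pairwise calls.
//
// PAIR nodes align only to PAIR nodes, UNPAIRED only to UNPAIRED; any node
// can align to a gap, in which case the children of a gapped PAIR node are
// promoted and aligned against a split of the opposing sibling forest.
//
// Subproblems are contiguous sibling intervals ("closed subforests"); the
// DP is memoised and the traceback re-derives decisions in a fixed
// preference order (match, gap-in-second, gap-in-first; split points in
// ascending order), so results are deterministic.

static const double FNEG = -1e18;
static const double FEPS2 = 1e-9;

struct ForestC {
  int n, r;
  std::vector<int> kind;                  // 1 = PAIR, 0 = UNPAIRED
  std::vector<std::vector<int> > kids;    // 0-based
  std::vector<int> top;
  std::vector<int> left, right;           // n*r, codes 0=gap,1..4
  // sibling lists: list 0 = top level, list v+1 = children of node v
  std::vector<std::vector<int> > lists;
  std::vector<long long> off;
  long long nsub;
  std::vector<double> gnode, gsub;        // gap cost per node / subtree
  std::vector<std::vector<double> > gpre; // prefix sums of gsub per list
  // residue-content counts for sigma: U nodes 5 bins, P nodes 17 bins
  std::vector<int> ucnt, pcnt;

  inline int L(int v, int rr) const { return left[(size_t)v * r + rr]; }
  inline int R(int v, int rr) const { return right[(size_t)v * r + rr]; }

  void build(List f) {
    IntegerVector k = f["kind"];
    n = k.size();
    kind.assign(k.begin(), k.end());
    List kd = f["kids"];
    kids.resize(n);
    for (int v = 0; v < n; ++v) {
      IntegerVector kv = kd[v];
      kids[v].resize(kv.size());
      for (int t = 0; t < kv.size(); ++t) kids[v][t] = kv[t] - 1;
    }
    IntegerVector tp = f["top"];
    top.resize(tp.size());
    for (int t = 0; t < tp.size(); ++t) top[t] = tp[t] - 1;
    IntegerMatrix lm = f["left"], rm = f["right"];
    r = lm.ncol();
    left.resize((size_t)n * r);
    right.resize((size_t)n * r);
    for (int v = 0; v < n; ++v)
      for (int rr = 0; rr < r; ++rr) {
        left[(size_t)v * r + rr] = lm(v, rr);
        right[(size_t)v * r + rr] = rm(v, rr);
      }
    lists.resize(n + 1);
    lists[0] = top;
    for (int v = 0; v < n; ++v) lists[v + 1] = kids[v];
    off.resize(n + 2);
    off[0] = 0;
    for (int l = 0; l <= n; ++l) {
      long long len = (long long)lists[l].size();
      off[l + 1] = off[l] + len * len;
    }
    nsub = off[n + 1];
    ucnt.assign((size_t)n * 5, 0);
    pcnt.assign((size_t)n * 17, 0);
    for (int v = 0; v < n; ++v)
      for (int rr = 0; rr < r; ++rr) {
        int a = L(v, rr), b = R(v, rr);
        if (kind[v] == 0) ucnt[(size_t)v * 5 + (a == 0 ? 4 : a - 1)]++;
        else pcnt[(size_t)v * 17 + (a == 0 ? 16 : (a - 1) * 4 + (b - 1))]++;
      }
  }

  void gapcosts(double pair_gap, double base_gap) {
    gnode.assign(n, 0.0);
    for (int v = 0; v < n; ++v) {
      int ng = 0;
      for (int rr = 0; rr < r; ++rr)
        if (L(v, rr) != 0) ng++;
      gnode[v] = ng * (kind[v] == 1 ? pair_gap : base_gap);
    }
    gsub.assign(n, 0.0);
    // children appear after their parent in no particular numeric order,
    // so accumulate by explicit post-order
    std::vector<int> st, order;
    for (size_t t = top.size(); t-- > 0;) st.push_back(top[t]);
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      order.push_back(v);
      for (size_t t = kids[v].size(); t-- > 0;) st.push_back(kids[v][t]);
    }
    for (size_t t = order.size(); t-- > 0;) {
      int v = order[t];
      double s = gnode[v];
      for (size_t c = 0; c < kids[v].size(); ++c) s += gsub[kids[v][c]];
      gsub[v] = s;
    }
    gpre.resize(n + 1);
    for (int l = 0; l <= n; ++l) {
      gpre[l].assign(lists[l].size() + 1, 0.0);
      for (size_t t = 0; t < lists[l].size(); ++t)
        gpre[l][t + 1] = gpre[l][t] + gsub[lists[l][t]];
    }
  }

  inline long long sid(int l, int s, int e) const {
    if (s > e) return -1;
    long long len = (long long)lists[l].size();
    return off[l] + (long long)s * len + e;
  }
  // decode id -> (l, s, e) via stored per-id tables (built lazily below)
};

struct ForestAligner {
  ForestC f1, f2;
  double pair_match, ident_bonus, base_match, base_mismatch, pair_gap,
      base_gap;
  std::unordered_map<long long, double> memo;
  std::vector<int> l1of, s1of, e1of, l2of, s2of, e2of;
  std::unordered_map<long long, double> sigcache;

  // output
  std::vector<int> okind, oparent;
  std::vector<std::vector<int> > oleft, oright;

  void decode_tables() {
    l1of.resize(f1.nsub); s1of.resize(f1.nsub); e1of.resize(f1.nsub);
    for (int l = 0; l <= f1.n; ++l) {
      int len = f1.lists[l].size();
      for (int s = 0; s < len; ++s)
        for (int e = 0; e < len; ++e) {
          long long id = f1.off[l] + (long long)s * len + e;
          l1of[id] = l; s1of[id] = s; e1of[id] = e;
        }
    }
    l2of.resize(f2.nsub); s2of.resize(f2.nsub); e2of.resize(f2.nsub);
    for (int l = 0; l <= f2.n; ++l) {
      int len = f2.lists[l].size();
      for (int s = 0; s < len; ++s)
        for (int e = 0; e < len; ++e) {
          long long id = f2.off[l] + (long long)s * len + e;
          l2of[id] = l; s2of[id] = s; e2of[id] = e;
        }
    }
  }

  double sigma(int a, int b) {
    if (f1.kind[a] != f2.kind[b]) return FNEG;
    long long key = (long long)a * f2.n + b;
    std::unordered_map<long long, double>::iterator it = sigcache.find(key);
    if (it != sigcache.end()) return it->second;
    double s = 0.0;
    if (f1.kind[a] == 0) {
      const int *ca = &f1.ucnt[(size_t)a * 5];
      const int *cb = &f2.ucnt[(size_t)b * 5];
      for (int x = 0; x < 4; ++x)
        for (int y = 0; y < 4; ++y)
          s += (double)ca[x] * cb[y] * (x == y ? base_match : base_mismatch);
      int nba = ca[0] + ca[1] + ca[2] + ca[3];
      int nbb = cb[0] + cb[1] + cb[2] + cb[3];
      s += (double)ca[4] * nbb * base_gap + (double)cb[4] * nba * base_gap;
    } else {
      const int *ca = &f1.pcnt[(size_t)a * 17];
      const int *cb = &f2.pcnt[(size_t)b * 17];
      int nba = 0, nbb = 0;
      for (int x = 0; x < 16; ++x) { nba += ca[x]; nbb += cb[x]; }
      for (int x = 0; x < 16; ++x) {
        if (!ca[x]) continue;
        for (int y = 0; y < 16; ++y) {
          if (!cb[y]) continue;
          s += (double)ca[x] * cb[y] *
               (pair_match + (x == y ? ident_bonus : 0.0));
        }
      }
      s += (double)ca[16] * nbb * pair_gap + (double)cb[16] * nba * pair_gap;
    }
    sigcache[key] = s;
    return s;
  }

  inline double gapAll1(long long x) const {
    if (x < 0) return 0.0;
    int l = l1of[x], s = s1of[x], e = e1of[x];
    return (f1.gpre[l][e + 1] - f1.gpre[l][s]) * f2.r;
  }
  inline double gapAll2(long long y) const {
    if (y < 0) return 0.0;
    int l = l2of[y], s = s2of[y], e = e2of[y];
    return (f2.gpre[l][e + 1] - f2.gpre[l][s]) * f1.r;
  }

  inline long long kidsSub1(int v) const {
    int deg = f1.kids[v].size();
    return deg ? f1.sid(v + 1, 0, deg - 1) : -1;
  }
  inline long long kidsSub2(int v) const {
    int deg = f2.kids[v].size();
    return deg ? f2.sid(v + 1, 0, deg - 1) : -1;
  }

  double S(long long x, long long y) {
    if (x < 0 && y < 0) return 0.0;
    if (x < 0) return gapAll2(y);
    if (y < 0) return gapAll1(x);
    long long key = (x + 1) * (f2.nsub + 1) + (y + 1);
    std::unordered_map<long long, double>::iterator it = memo.find(key);
    if (it != memo.end()) return it->second;

    int l1 = l1of[x], s1 = s1of[x], e1 = e1of[x];
    int l2 = l2of[y], s2 = s2of[y], e2 = e2of[y];
    int a = f1.lists[l1][s1], b = f2.lists[l2][s2];
    long long kA = kidsSub1(a), kB = kidsSub2(b);
    long long rA = (s1 < e1) ? f1.sid(l1, s1 + 1, e1) : -1;
    long long rB = (s2 < e2) ? f2.sid(l2, s2 + 1, e2) : -1;

    double best = FNEG;
    if (f1.kind[a] == f2.kind[b]) {
      double v = sigma(a, b) + S(kA, kB) + S(rA, rB);
      if (v > best) best = v;
    }
    // a aligned to gap: children of a face a split of the opposing forest
    for (int k = s2 - 1; k <= e2; ++k) {
      long long g1 = (k >= s2) ? f2.sid(l2, s2, k) : -1;
      long long g2 = (k + 1 <= e2) ? f2.sid(l2, k + 1, e2) : -1;
      double v = f1.gnode[a] * f2.r + S(kA, g1) + S(rA, g2);
      if (v > best) best = v;
    }
    // b aligned to gap
    for (int k = s1 - 1; k <= e1; ++k) {
      long long g1 = (k >= s1) ? f1.sid(l1, s1, k) : -1;
      long long g2 = (k + 1 <= e1) ? f1.sid(l1, k + 1, e1) : -1;
      double v = f2.gnode[b] * f1.r + S(g1, kB) + S(g2, rB);
      if (v > best) best = v;
    }
    memo[key] = best;
    return best;
  }

  int emitNode(int kind, int parent, const int *l1row, const int *r1row,
               const int *l2row, const int *r2row) {
    okind.push_back(kind);
    oparent.push_back(parent);
    std::vector<int> lr(f1.r + f2.r, 0), rr(f1.r + f2.r, 0);
    for (int t = 0; t < f1.r; ++t) {
      lr[t] = l1row ? l1row[t] : 0;
      rr[t] = r1row ? r1row[t] : 0;
    }
    for (int t = 0; t < f2.r; ++t) {
      lr[f1.r + t] = l2row ? l2row[t] : 0;
      rr[f1.r + t] = r2row ? r2row[t] : 0;
    }
    oleft.push_back(lr);
    oright.push_back(rr);
    return (int)okind.size();  // 1-based id of the emitted node
  }

  void emitCopy1(long long x, int parent) {
    if (x < 0) return;
    int l = l1of[x], s = s1of[x], e = e1of[x];
    for (int t = s; t <= e; ++t) {
      int v = f1.lists[l][t];
      int me = emitNode(f1.kind[v], parent, &f1.left[(size_t)v * f1.r],
                        &f1.right[(size_t)v * f1.r], NULL, NULL);
      emitCopy1(kidsSub1(v), me);
    }
  }
  void emitCopy2(long long y, int parent) {
    if (y < 0) return;
    int l = l2of[y], s = s2of[y], e = e2of[y];
    for (int t = s; t <= e; ++t) {
      int v = f2.lists[l][t];
      int me = emitNode(f2.kind[v], parent, NULL, NULL,
                        &f2.left[(size_t)v * f2.r],
                        &f2.right[(size_t)v * f2.r]);
      emitCopy2(kidsSub2(v), me);
    }
  }

  void trace(long long x, long long y, int parent) {
    if (x < 0 && y < 0) return;
    if (x < 0) { emitCopy2(y, parent); return; }
    if (y < 0) { emitCopy1(x, parent); return; }
    double target = S(x, y);
    int l1 = l1of[x], s1 = s1of[x], e1 = e1of[x];
    int l2 = l2of[y], s2 = s2of[y], e2 = e2of[y];
    int a = f1.lists[l1][s1], b = f2.lists[l2][s2];
    long long kA = kidsSub1(a), kB = kidsSub2(b);
    long long rA = (s1 < e1) ? f1.sid(l1, s1 + 1, e1) : -1;
    long long rB = (s2 < e2) ? f2.sid(l2, s2 + 1, e2) : -1;

    if (f1.kind[a] == f2.kind[b]) {
      double v = sigma(a, b) + S(kA, kB) + S(rA, rB);
      if (std::fabs(v - target) <= FEPS2) {
        int me = emitNode(f1.kind[a], parent, &f1.left[(size_t)a * f1.r],
                          &f1.right[(size_t)a * f1.r],
                          &f2.left[(size_t)b * f2.r],
                          &f2.right[(size_t)b * f2.r]);
        trace(kA, kB, me);
        trace(rA, rB, parent);
        return;
      }
    }
    for (int k = s2 - 1; k <= e2; ++k) {
      long long g1 = (k >= s2) ? f2.sid(l2, s2, k) : -1;
      long long g2 = (k + 1 <= e2) ? f2.sid(l2, k + 1, e2) : -1;
      double v = f1.gnode[a] * f2.r + S(kA, g1) + S(rA, g2);
      if (std::fabs(v - target) <= FEPS2) {
        int me = emitNode(f1.kind[a], parent, &f1.left[(size_t)a * f1.r],
                          &f1.right[(size_t)a * f1.r], NULL, NULL);
        trace(kA, g1, me);
        trace(rA, g2, parent);
        return;
      }
    }
    for (int k = s1 - 1; k <= e1; ++k) {
      long long g1 = (k >= s1) ? f1.sid(l1, s1, k) : -1;
      long long g2 = (k + 1 <= e1) ? f1.sid(l1, k + 1, e1) : -1;
      double v = f2.gnode[b] * f1.r + S(g1, kB) + S(g2, rB);
      if (std::fabs(v - target) <= FEPS2) {
        int me = emitNode(f2.kind[b], parent, NULL, NULL,
                          &f2.left[(size_t)b * f2.r],
                          &f2.right[(size_t)b * f2.r]);
        trace(g1, kB, me);
        trace(g2, rB, parent);
        return;
      }
    }
    stop("forest traceback failed (internal error)");
  }
};

// [[Rcpp::export]]
List forest_align_cpp(List forest1, List forest2, List score) {
  ForestAligner al;
  al.f1.build(forest1);
  al.f2.build(forest2);
  al.pair_match = as<double>(score["pair_match"]);
  al.ident_bonus = as<double>(score["pair_ident_bonus"]);
  al.base_match = as<double>(score["base_match"]);
  al.base_mismatch = as<double>(score["base_mismatch"]);
  al.pair_gap = as<double>(score["pair_gap"]);
  al.base_gap = as<double>(score["base_gap"]);
  al.f1.gapcosts(al.pair_gap, al.base_gap);
  al.f2.gapcosts(al.pair_gap, al.base_gap);
  al.decode_tables();

  long long x = al.f1.top.empty()
                    ? -1
                    : al.f1.sid(0, 0, (int)al.f1.top.size() - 1);
  long long y = al.f2.top.empty()
                    ? -1
                    : al.f2.sid(0, 0, (int)al.f2.top.size() - 1);
  double sc = al.S(x, y);
  al.trace(x, y, 0);

  int nn = al.okind.size();
  int rr = al.f1.r + al.f2.r;
  IntegerMatrix lm(nn, rr), rm(nn, rr);
  IntegerVector kind(nn), parent(nn);
  for (int v = 0; v < nn; ++v) {
    kind[v] = al.okind[v];
    parent[v] = al.oparent[v];
    for (int t = 0; t < rr; ++t) {
      lm(v, t) = al.oleft[v][t];
      rm(v, t) = al.oright[v][t];
    }
  }
  return List::create(_["score"] = sc, _["kind"] = kind,
                      _["parent"] = parent, _["left"] = lm,
                      _["right"] = rm);
}
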