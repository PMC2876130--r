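#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimum-energy nested-structure DP over an arbitrary pair-score matrix.
// Shared by single-sequence MFE folding, constrained folding (forbidden
// entries express the constraints) and consensus folding of an alignment
// (scores are column pseudo-energies).
//
// S[i][j] finite  <=> positions i<j may pair, at that base energy.
// unpaired_ok[i]  <=> position i may stay unpaired (FALSE for positions
//                     that carry a mandatory pair).
// stack_bonus     <=  0, added when (i,j) and (i+1,j-1) are both paired.
//
// Objective: lexicographic minimum of (energy, number of pairs); ties beyond
// that are resolved by a fixed traceback order (unpaired end first, then the
// smallest opening position), so results are deterministic.

static const double FINF = 1e18;
static const double FEPS = 1e-9;

struct FoldDP {
  int n;
  const NumericMatrix &S;
  const LogicalVector &unp;
  double stack;
  std::vector<double> W, V;
  std::vector<int> Wn, Vn;

  FoldDP(const NumericMatrix &S_, const LogicalVector &unp_, double stack_)
    : n(S_.nrow()), S(S_), unp(unp_), stack(stack_),
      W(n * n, 0.0), V(n * n, FINF), Wn(n * n, 0), Vn(n * n, 0) {}

  inline int id(int i, int j) const { return i * n + j; }
  inline bool allowed(int i, int j) const {
    double s = S(i, j);
    return R_finite(s);
  }
  // lexicographic (energy, count) comparison: a <= b
  static inline bool lexle(double ea, int na, double eb, int nb) {
    if (ea < eb - FEPS) return true;
    if (ea > eb + FEPS) return false;
    return na <= nb;
  }
  static inline bool lexeq(double ea, int na, double eb, int nb) {
    return std::fabs(ea - eb) <= FEPS && na == nb;
  }

  inline double Wat(int i, int j, int &cnt) const {
    if (i > j) { cnt = 0; return 0.0; }
    cnt = Wn[id(i, j)];
    return W[id(i, j)];
  }

  void run() {
    for (int span = 1; span <= n; ++span) {
      for (int i = 0; i + span - 1 < n; ++i) {
        int j = i + span - 1;
        // V(i,j): (i,j) paired
        if (allowed(i, j)) {
          double be;
          int bn;
          if (i + 1 > j - 1) {
            be = 0.0; bn = 0;
          } else {
            int wc;
            double we = Wat(i + 1, j - 1, wc);
            be = we; bn = wc;
            double vi = V[id(i + 1, j - 1)];
            if (vi < FINF / 2) {
              double ve = vi + stack;
              int vc = Vn[id(i + 1, j - 1)];
              if (!lexle(be, bn, ve, vc)) { be = ve; bn = vc; }
            }
          }
          if (be < FINF / 2) {
            V[id(i, j)] = S(i, j) + be;
            Vn[id(i, j)] = bn + 1;
          }
        }
        // W(i,j)
        double be = FINF;
        int bn = 0;
        if (unp[j]) {
          int wc;
          double we = Wat(i, j - 1, wc);
          be = we; bn = wc;
        }
        for (int k = i; k <= j; ++k) {
          double v = V[id(k, j)];
          if (v >= FINF / 2) continue;
          int wc;
          double we = Wat(i, k - 1, wc);
          if (we >= FINF / 2) continue;
          double e = we + v;
          int c = wc + Vn[id(k, j)];
          if (!lexle(be, bn, e, c)) { be = e; bn = c; }
        }
        W[id(i, j)] = be;
        Wn[id(i, j)] = bn;
      }
    }
  }

  void tbV(int i, int j, std::vector<std::pair<int,int> > &out) const {
    out.push_back(std::make_pair(i, j));
    if (i + 1 > j - 1) return;
    double target = V[id(i, j)] - S(i, j);
    int tn = Vn[id(i, j)] - 1;
    int wc;
    double we = Wat(i + 1, j - 1, wc);
    if (we < FINF / 2 && lexeq(we, wc, target, tn)) {
      tbW(i + 1, j - 1, out);
      return;
    }
    // stacked route
    tbV(i + 1, j - 1, out);
  }

  void tbW(int i, int j, std::vector<std::pair<int,int> > &out) const {
    if (i > j) return;
    double t = W[id(i, j)];
    int tn = Wn[id(i, j)];
    if (unp[j]) {
      int wc;
      double we = Wat(i, j - 1, wc);
      if (lexeq(we, wc, t, tn)) { tbW(i, j - 1, out); return; }
    }
    for (int k = i; k <= j; ++k) {
      double v = V[id(k, j)];
      if (v >= FINF / 2) continue;
      int wc;
      double we = Wat(i, k - 1, wc);
      if (we >= FINF / 2) continue;
      if (lexeq(we + v, wc + Vn[id(k, j)], t, tn)) {
        tbW(i, k - 1, out);
        tbV(k, j, out);
        return;
      }
    }
    stop("fold traceback failed (internal error)");
  }
};

// [[Rcpp::export]]
List fold_dp_cpp(NumericMatrix S, LogicalVector unpaired_ok, double stack_bonus) {
  int n = S.nrow();
  if (n == 0)
    return List::create(_["pairs"] = IntegerMatrix(0, 2),
                        _["energy"] = 0.0, _["npairs"] = 0);
  if (S.ncol() != n || unpaired_ok.size() != n)
    stop("inconsistent DP inputs");
  FoldDP dp(S, unpaired_ok, stack_bonus);
  dp.run();
  double e = dp.W[dp.id(0, n - 1)];
  if (e >= FINF / 2)
    stop("no feasible structure under the given constraints");
  std::vector<std::pair<int,int> > pr;
  dp.tbW(0, n - 1, pr);
  IntegerMatrix pairs(pr.size(), 2);
  for (size_t k = 0; k < pr.size(); ++k) {
    pairs(k, 0) = pr[k].first + 1;  // back to 1-based for R
    pairs(k, 1) = pr[k].second + 1;
  }
  return List::create(_["pairs"] = pairs, _["energy"] = e,
                      _["npairs"] = (int)pr.size());
}
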