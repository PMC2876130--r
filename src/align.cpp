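#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Global affine-gap profile-profile alignment (Gotoh), sum-of-pairs
// substitution scores. The DP runs over suffixes so the traceback walks
// left-to-right, which lets the tie-break rule "prefer diagonal, then
// gap-in-<preferred row set>, resolved left-to-right" be applied literally.
//
// Profiles are integer matrices (rows x columns), codes 0 = gap, 1..4 =
// A,C,G,U. Substitution score between two columns sums match/mismatch over
// all residue pairs (gap entries contribute nothing). Gap penalties for
// consuming a column are scaled by (#non-gap entries in the consumed
// column) * (number of rows of the other profile), so that for two
// single-sequence profiles the scheme reduces to plain pairwise Gotoh.
// A gap run of length k costs open + (k-1)*extend (times the weights; the
// open surcharge is booked on the last column of the run).

static const double NEG = -1e18;
static const double AEPS = 1e-9;

// [[Rcpp::export]]
List gotoh_align_cpp(IntegerMatrix A, IntegerMatrix B,
                     double match, double mismatch,
                     double gap_open, double gap_extend,
                     bool prefer_gap_in_B) {
  const int rA = A.nrow(), cA = A.ncol();
  const int rB = B.nrow(), cB = B.ncol();
  if (cA == 0 || cB == 0) stop("empty profile");

  std::vector<int> cntA(cA * 4, 0), cntB(cB * 4, 0);
  std::vector<double> wA(cA), wB(cB);
  for (int j = 0; j < cA; ++j) {
    int ng = 0;
    for (int r = 0; r < rA; ++r) {
      int v = A(r, j);
      if (v >= 1 && v <= 4) { cntA[j * 4 + v - 1]++; ng++; }
    }
    wA[j] = (double)ng * rB;
  }
  for (int j = 0; j < cB; ++j) {
    int ng = 0;
    for (int r = 0; r < rB; ++r) {
      int v = B(r, j);
      if (v >= 1 && v <= 4) { cntB[j * 4 + v - 1]++; ng++; }
    }
    wB[j] = (double)ng * rA;
  }
  std::vector<double> sub((size_t)cA * cB);
  for (int i = 0; i < cA; ++i)
    for (int j = 0; j < cB; ++j) {
      double s = 0.0;
      for (int x = 0; x < 4; ++x) {
        int ca = cntA[i * 4 + x];
        if (!ca) continue;
        for (int y = 0; y < 4; ++y) {
          int cb = cntB[j * 4 + y];
          if (!cb) continue;
          s += (double)ca * cb * (x == y ? match : mismatch);
        }
      }
      sub[(size_t)i * cB + j] = s;
    }

  // Suffix DP. D = first column is diagonal; E = first column consumes A
  // (gap character in B); F = first column consumes B.
  const size_t NC = (size_t)(cA + 1) * (cB + 1);
  std::vector<double> D(NC, NEG), E(NC, NEG), F(NC, NEG), H(NC, NEG);
  #define IDX(i, j) ((size_t)(i) * (cB + 1) + (j))

  // value of "the run exits here": best of D/F (for E) at the next cell,
  // or 0 exactly at the terminal corner
  H[IDX(cA, cB)] = 0.0;
  for (int i = cA; i >= 0; --i) {
    for (int j = cB; j >= 0; --j) {
      if (i == cA && j == cB) continue;
      double d = NEG, e = NEG, f = NEG;
      if (i < cA && j < cB)
        d = sub[(size_t)i * cB + j] + H[IDX(i + 1, j + 1)];
      if (i < cA) {
        double op = (i + 1 == cA && j == cB)
                      ? 0.0
                      : std::max(D[IDX(i + 1, j)], F[IDX(i + 1, j)]);
        double ex = E[IDX(i + 1, j)];
        e = std::max(op > NEG / 2 ? wA[i] * gap_open + op : NEG,
                     ex > NEG / 2 ? wA[i] * gap_extend + ex : NEG);
      }
      if (j < cB) {
        double op = (i == cA && j + 1 == cB)
                      ? 0.0
                      : std::max(D[IDX(i, j + 1)], E[IDX(i, j + 1)]);
        double ex = F[IDX(i, j + 1)];
        f = std::max(op > NEG / 2 ? wB[j] * gap_open + op : NEG,
                     ex > NEG / 2 ? wB[j] * gap_extend + ex : NEG);
      }
      D[IDX(i, j)] = d;
      E[IDX(i, j)] = e;
      F[IDX(i, j)] = f;
      H[IDX(i, j)] = std::max(d, std::max(e, f));
    }
  }
  double best = H[IDX(0, 0)];

  // Forward traceback. mode: 0 = free {D,E,F}, 1 = must continue E,
  // 2 = must continue F, 3 = E just exited (choose D or F),
  // 4 = F just exited (choose D or E).
  std::vector<int> ai, bi;
  int i = 0, j = 0, mode = 0;
  while (!(i == cA && j == cB)) {
    bool mayD = (i < cA && j < cB) && (mode == 0 || mode == 3 || mode == 4);
    bool mayE = (i < cA) && (mode == 0 || mode == 1 || mode == 4);
    bool mayF = (j < cB) && (mode == 0 || mode == 2 || mode == 3);
    double target;
    if (mode == 1) target = E[IDX(i, j)];
    else if (mode == 2) target = F[IDX(i, j)];
    else if (mode == 3) target = std::max(D[IDX(i, j)], F[IDX(i, j)]);
    else if (mode == 4) target = std::max(D[IDX(i, j)], E[IDX(i, j)]);
    else target = H[IDX(i, j)];

    int pick = -1;  // 0 = D, 1 = E, 2 = F
    if (mayD && std::fabs(D[IDX(i, j)] - target) <= AEPS) pick = 0;
    if (pick < 0) {
      int first = prefer_gap_in_B ? 1 : 2, second = prefer_gap_in_B ? 2 : 1;
      if (first == 1 ? mayE : mayF) {
        double v = first == 1 ? E[IDX(i, j)] : F[IDX(i, j)];
        if (std::fabs(v - target) <= AEPS) pick = first;
      }
      if (pick < 0 && (second == 1 ? mayE : mayF)) {
        double v = second == 1 ? E[IDX(i, j)] : F[IDX(i, j)];
        if (std::fabs(v - target) <= AEPS) pick = second;
      }
    }
    if (pick < 0) stop("alignment traceback failed (internal error)");

    if (pick == 0) {
      ai.push_back(i + 1); bi.push_back(j + 1); ++i; ++j; mode = 0;
    } else if (pick == 1) {
      double op = (i + 1 == cA && j == cB)
                    ? 0.0
                    : std::max(D[IDX(i + 1, j)], F[IDX(i + 1, j)]);
      double val = E[IDX(i, j)];
      // prefer exiting the run (shorter gap runs) at exact ties
      if (op > NEG / 2 && std::fabs(val - (wA[i] * gap_open + op)) <= AEPS)
        mode = 3;
      else
        mode = 1;
      ai.push_back(i + 1); bi.push_back(0); ++i;
    } else {
      double op = (i == cA && j + 1 == cB)
                    ? 0.0
                    : std::max(D[IDX(i, j + 1)], E[IDX(i, j + 1)]);
      double val = F[IDX(i, j)];
      if (op > NEG / 2 && std::fabs(val - (wB[j] * gap_open + op)) <= AEPS)
        mode = 4;
      else
        mode = 2;
      ai.push_back(0); bi.push_back(j + 1); ++j;
    }
  }

  return List::create(_["score"] = best,
                      _["ai"] = IntegerVector(ai.begin(), ai.end()),
                      _["bi"] = IntegerVector(bi.begin(), bi.end()));
}
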