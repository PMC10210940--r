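#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Glocal (full model, free flanks) scoring of a sequence against a profile
// HMM, in log2-odds space. The model must be traversed from node 1 to node L
// (deletions allowed); unannotated sequence flanks are emitted at background
// frequencies and contribute 0 bits.
//
// Inputs are log2-odds / log2-probability matrices prepared in R:
//   lmatch: L x 20, log2(match_emission / background)
//   lins:  (L+1) x 20, log2(insert_emission / background), row k = insert k
//   ltr:   (L+1) x 7, log2 transition probabilities, columns
//          MM MI MD IM II DM DD for node k = 0..L (node 0 = begin; at node L,
//          MM/IM/DM are the exits to E and MD/DD are -Inf)
//   seq: 0-based residue codes, -1 for X (emits background: 0 bits)
//
// mode 0 = Viterbi (max), 1 = Forward (log-sum).

static const double NEG = -1e100;

static inline double lse2(double a, double b) {
  double m = a > b ? a : b;
  if (!std::isfinite(m) || m < -1e99) return m;  // both effectively zero
  return m + std::log2(std::exp2(a - m) + std::exp2(b - m));
}
static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// [[Rcpp::export(name = ".hmm_score_cpp")]]
double hmm_score_cpp(NumericMatrix lmatch, NumericMatrix lins,
                     NumericMatrix ltr, IntegerVector seq, int mode) {
  const int L = lmatch.nrow(), n = seq.size();
  const int MM = 0, MI = 1, MD = 2, IM = 3, II = 4, DM = 5, DD = 6;
  // state matrices over nodes 0..L and prefix lengths 0..n
  NumericMatrix vM(L + 1, n + 1), vI(L + 1, n + 1), vD(L + 1, n + 1);
  for (int k = 0; k <= L; ++k)
    for (int i = 0; i <= n; ++i) { vM(k, i) = NEG; vI(k, i) = NEG; vD(k, i) = NEG; }
  // node 0 = begin, reachable after any number of free flank residues
  for (int i = 0; i <= n; ++i) vM(0, i) = 0.0;
  // insert state at node 0
  for (int i = 1; i <= n; ++i) {
    int r = seq[i - 1];
    double e = (r < 0) ? 0.0 : lins(0, r);
    double stay = vI(0, i - 1) + ltr(0, II);
    double openi = vM(0, i - 1) + ltr(0, MI);
    vI(0, i) = e + (mode == 0 ? std::max(stay, openi) : lse2(stay, openi));
  }
  for (int k = 1; k <= L; ++k) {
    // delete column (consumes nothing)
    for (int i = 0; i <= n; ++i) {
      double fromM = vM(k - 1, i) + ltr(k - 1, MD);
      double fromD = (k >= 2) ? vD(k - 1, i) + ltr(k - 1, DD) : NEG;
      vD(k, i) = (mode == 0) ? std::max(fromM, fromD) : lse2(fromM, fromD);
    }
    // match column
    for (int i = 1; i <= n; ++i) {
      int r = seq[i - 1];
      double e = (r < 0) ? 0.0 : lmatch(k - 1, r);
      double a = vM(k - 1, i - 1) + ltr(k - 1, MM);
      double b = vI(k - 1, i - 1) + ltr(k - 1, IM);
      double c = vD(k - 1, i - 1) + ltr(k - 1, DM);
      vM(k, i) = e + (mode == 0 ? std::max(a, std::max(b, c)) : lse3(a, b, c));
    }
    // insert column at node k
    for (int i = 1; i <= n; ++i) {
      int r = seq[i - 1];
      double e = (r < 0) ? 0.0 : lins(k, r);
      double stay = vI(k, i - 1) + ltr(k, II);
      double openi = vM(k, i - 1) + ltr(k, MI);
      vI(k, i) = e + (mode == 0 ? std::max(stay, openi) : lse2(stay, openi));
    }
  }
  // exit to E from node L (MM/IM/DM columns), C flank free
  double out = NEG;
  for (int i = 0; i <= n; ++i) {
    double a = vM(L, i) + ltr(L, MM);
    double b = vI(L, i) + ltr(L, IM);
    double c = vD(L, i) + ltr(L, DM);
    double e = (mode == 0) ? std::max(a, std::max(b, c)) : lse3(a, b, c);
    out = (mode == 0) ? std::max(out, e) : lse2(out, e);
  }
  return out;
}
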