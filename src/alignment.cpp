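#include <Rcpp.h>
using namespace Rcpp;

// Affine gap convention throughout: a gap of length g costs open + g * extend
// (opening move costs open + extend, each continuation costs extend).

// Smith-Waterman local alignment with affine gaps.
// qi, si: 0-based integer-encoded sequences; sub: square substitution matrix
// indexed by those codes. Traceback tie-break: diagonal > up (gap in subject)
// > left (gap in query); best cell ties resolved by smallest i, then j.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector qi, IntegerVector si, NumericMatrix sub,
                  double open, double extend) {
  const int m = qi.size(), n = si.size();
  const double og = open + extend, eg = extend;
  NumericMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  // pointer codes for H: 0 stop, 1 diag, 2 up(F), 3 left(E)
  IntegerMatrix PH(m + 1, n + 1);
  // pointers for E/F: 1 = came from H (gap opened), 0 = extended
  IntegerMatrix PE(m + 1, n + 1), PF(m + 1, n + 1);
  const double NEG = -1e100;
  for (int j = 0; j <= n; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= m; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (consume subject residue j)
      double eo = H(i, j - 1) - og, ee = E(i, j - 1) - eg;
      if (eo >= ee) { E(i, j) = eo; PE(i, j) = 1; } else { E(i, j) = ee; PE(i, j) = 0; }
      // F: gap in subject (consume query residue i)
      double fo = H(i - 1, j) - og, fe = F(i - 1, j) - eg;
      if (fo >= fe) { F(i, j) = fo; PF(i, j) = 1; } else { F(i, j) = fe; PF(i, j) = 0; }
      double diag = H(i - 1, j - 1) + sub(qi[i - 1], si[j - 1]);
      // preference: diag > up > left > stop at equal score
      double h = 0.0; int p = 0;
      if (diag >= h) { h = diag; p = 1; }
      if (F(i, j) > h) { h = F(i, j); p = 2; }
      if (E(i, j) > h) { h = E(i, j); p = 3; }
      H(i, j) = h; PH(i, j) = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback: rq/rs mark per-column residue consumption (1) vs gap (0)
  std::vector<int> rq, rs;
  int qs = 0, qe = 0, ss = 0, se = 0;
  if (best > 0.0) {
    int i = bi, j = bj; char state = 'H';
    while (true) {
      if (state == 'H') {
        int p = PH(i, j);
        if (p == 0) break;
        if (p == 1) { rq.push_back(1); rs.push_back(1); --i; --j; }
        else if (p == 2) state = 'F';
        else state = 'E';
      } else if (state == 'F') {
        rq.push_back(1); rs.push_back(0);
        if (PF(i, j) == 1) state = 'H';
        --i;
      } else { // E
        rq.push_back(0); rs.push_back(1);
        if (PE(i, j) == 1) state = 'H';
        --j;
      }
    }
    qs = i + 1; ss = j + 1; qe = bi; se = bj;
  }
  IntegerVector opsq(rq.size()), opss(rs.size());
  for (size_t k = 0; k < rq.size(); ++k) {
    opsq[k] = rq[rq.size() - 1 - k];
    opss[k] = rs[rs.size() - 1 - k];
  }
  return List::create(_["score"] = best, _["q_start"] = qs, _["q_end"] = qe,
                      _["s_start"] = ss, _["s_end"] = se,
                      _["q_ops"] = opsq, _["s_ops"] = opss);
}

// Global (Needleman-Wunsch-Gotoh) profile-profile alignment.
// pa: La x A frequency matrix, pb: Lb x A, sub: A x A. Terminal gaps are
// penalized. Returns the op path: 0 = column from both, 1 = column from A
// only (gap in B), 2 = column from B only (gap in A).
// Tie-break: diag > up (A-only) > left (B-only).
// [[Rcpp::export(name = ".profile_align_cpp")]]
IntegerVector profile_align_cpp(NumericMatrix pa, NumericMatrix pb,
                                NumericMatrix sub, double open, double extend) {
  const int m = pa.nrow(), n = pb.nrow(), A = sub.nrow();
  const double og = open + extend, eg = extend, NEG = -1e100;
  // expected score of A-column i against residue r
  NumericMatrix SA(m, A);
  for (int i = 0; i < m; ++i)
    for (int r = 0; r < A; ++r) {
      double s = 0.0;
      for (int a = 0; a < A; ++a) s += pa(i, a) * sub(a, r);
      SA(i, r) = s;
    }
  NumericMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  IntegerMatrix PH(m + 1, n + 1), PE(m + 1, n + 1), PF(m + 1, n + 1);
  H(0, 0) = 0; E(0, 0) = NEG; F(0, 0) = NEG;
  for (int j = 1; j <= n; ++j) {
    E(0, j) = -og - eg * (j - 1); H(0, j) = E(0, j); F(0, j) = NEG;
    PH(0, j) = 3; PE(0, j) = (j == 1) ? 1 : 0;
  }
  for (int i = 1; i <= m; ++i) {
    F(i, 0) = -og - eg * (i - 1); H(i, 0) = F(i, 0); E(i, 0) = NEG;
    PH(i, 0) = 2; PF(i, 0) = (i == 1) ? 1 : 0;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double eo = H(i, j - 1) - og, ee = E(i, j - 1) - eg;
      if (eo >= ee) { E(i, j) = eo; PE(i, j) = 1; } else { E(i, j) = ee; PE(i, j) = 0; }
      double fo = H(i - 1, j) - og, fe = F(i - 1, j) - eg;
      if (fo >= fe) { F(i, j) = fo; PF(i, j) = 1; } else { F(i, j) = fe; PF(i, j) = 0; }
      double sc = 0.0;
      for (int r = 0; r < A; ++r) sc += pb(j - 1, r) * SA(i - 1, r);
      double diag = H(i - 1, j - 1) + sc;
      double h = diag; int p = 1;
      if (F(i, j) > h) { h = F(i, j); p = 2; }
      if (E(i, j) > h) { h = E(i, j); p = 3; }
      H(i, j) = h; PH(i, j) = p;
    }
  }
  std::vector<int> rev;
  int i = m, j = n; char state = 'H';
  while (i > 0 || j > 0) {
    if (state == 'H') {
      int p = PH(i, j);
      if (p == 1) { rev.push_back(0); --i; --j; }
      else if (p == 2) state = 'F';
      else state = 'E';
    } else if (state == 'F') {
      rev.push_back(1);
      if (PF(i, j) == 1) state = 'H';
      --i;
    } else {
      rev.push_back(2);
      if (PE(i, j) == 1) state = 'H';
      --j;
    }
  }
  IntegerVector ops(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) ops[k] = rev[rev.size() - 1 - k];
  return ops;
}
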