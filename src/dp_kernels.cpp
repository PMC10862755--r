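// Dynamic-programming kernels: full and sparse Forward/Backward/Viterbi,
// posterior-gain (MEA) alignment, seeded anti-diagonal cloud search, and
// batch scoring loops used for null calibration.
//
// Conventions shared with the R wrappers:
//  * all values are natural-log odds (nats); -Inf is "probability zero";
//  * profiles arrive pre-converted ("prepared") as log-odds matrices:
//      msc, isc : (m+1) x (K+1) emission log-odds, row 0 = -Inf,
//                 last column = wildcard residue scored 0 (background);
//      tr       : (m+1) x 7 log transitions, column order
//                 MM, MD, MI, II, IM, DD, DM (row i = transitions out of
//                 node i; row 0 = begin node);
//      entry    : (m+1) log local-entry probabilities B -> M_i;
//  * target sequences are 1-based integer vectors, K+1 = wildcard;
//  * matrices are (m+1) x (n+1); row/column 0 is the begin boundary.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// transition column indices (see above)
enum { TMM = 0, TMD = 1, TMI = 2, TII = 3, TIM = 4, TDD = 5, TDM = 6 };

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + log1p(std::exp(b - a));
}
static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}
static inline double lse4(double a, double b, double c, double d) {
  return lse2(lse2(a, b), lse2(c, d));
}

struct Prof {
  NumericMatrix msc, isc, tr;
  NumericVector entry;
  int m, K; // K = alphabet size incl. wildcard column count - 1
  Prof(List prof)
      : msc(as<NumericMatrix>(prof["msc"])),
        isc(as<NumericMatrix>(prof["isc"])),
        tr(as<NumericMatrix>(prof["tr"])),
        entry(as<NumericVector>(prof["entry"])) {
    m = msc.nrow() - 1;
    K = msc.ncol();
  }
};

// target-length dependent special-state loop scores (unihit local mode)
struct Specials {
  double lnNN, lnNB, lnCC, lnCT;
  Specials(int n) {
    lnNN = std::log((double)n / (n + 2.0));
    lnNB = std::log(2.0 / (n + 2.0));
    lnCC = lnNN;
    lnCT = lnNB;
  }
};

// ---------------------------------------------------------------------------
// full-matrix Forward
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_forward(List prof, IntegerVector seq, bool local,
                 bool antidiag_order, bool want_matrices) {
  Prof P(prof);
  int m = P.m, n = seq.size();
  Specials sp(n);

  NumericMatrix M(m + 1, n + 1), I(m + 1, n + 1), D(m + 1, n + 1);
  std::fill(M.begin(), M.end(), NEG_INF);
  std::fill(I.begin(), I.end(), NEG_INF);
  std::fill(D.begin(), D.end(), NEG_INF);
  NumericVector sN(n + 1, NEG_INF), sB(n + 1, NEG_INF), sE(n + 1, NEG_INF),
      sC(n + 1, NEG_INF);

  if (local) {
    sN[0] = 0.0;
    sB[0] = sN[0] + sp.lnNB;
    for (int j = 1; j <= n; ++j) {
      sN[j] = sN[j - 1] + sp.lnNN;
      sB[j] = sN[j] + sp.lnNB;
    }
  } else {
    M(0, 0) = I(0, 0) = D(0, 0) = 0.0;
    for (int i = 1; i <= m; ++i)
      D(i, 0) = lse2(M(i - 1, 0) + P.tr(i - 1, TMD),
                     D(i - 1, 0) + P.tr(i - 1, TDD));
    for (int j = 1; j <= n; ++j) {
      int c = seq[j - 1] - 1;
      I(0, j) = P.isc(0, c) +
                lse2(M(0, j - 1) + P.tr(0, TMI), I(0, j - 1) + P.tr(0, TII));
    }
  }

  // core cell update, identical under either fill order
  auto fill_cell = [&](int i, int j) {
    int c = seq[j - 1] - 1;
    double mval = lse3(M(i - 1, j - 1) + P.tr(i - 1, TMM),
                       I(i - 1, j - 1) + P.tr(i - 1, TIM),
                       D(i - 1, j - 1) + P.tr(i - 1, TDM));
    if (local) mval = lse2(mval, sB[j - 1] + P.entry[i]);
    M(i, j) = P.msc(i, c) + mval;
    I(i, j) = P.isc(i, c) +
              lse2(M(i, j - 1) + P.tr(i, TMI), I(i, j - 1) + P.tr(i, TII));
    D(i, j) = lse2(M(i - 1, j) + P.tr(i - 1, TMD),
                   D(i - 1, j) + P.tr(i - 1, TDD));
  };

  if (!antidiag_order) {
    for (int i = 1; i <= m; ++i)
      for (int j = 1; j <= n; ++j) fill_cell(i, j);
  } else {
    for (int d = 2; d <= m + n; ++d) {
      int ilo = std::max(1, d - n), ihi = std::min(m, d - 1);
      for (int i = ilo; i <= ihi; ++i) fill_cell(i, d - i);
    }
  }

  double score;
  if (local) {
    for (int j = 1; j <= n; ++j) {
      double e = NEG_INF;
      for (int i = 1; i <= m; ++i) e = lse2(e, M(i, j)); // exit score 0
      sE[j] = e;
      sC[j] = lse2(sC[j - 1] + sp.lnCC, sE[j]);
    }
    score = sC[n] + sp.lnCT;
  } else {
    score = lse3(M(m, n) + P.tr(m, TMM), I(m, n) + P.tr(m, TIM),
                 D(m, n) + P.tr(m, TDM));
  }

  List out = List::create(
      _["score"] = score,
      _["specials"] = List::create(_["N"] = sN, _["B"] = sB, _["E"] = sE,
                                   _["C"] = sC));
  if (want_matrices) {
    out["M"] = M;
    out["I"] = I;
    out["D"] = D;
  }
  return out;
}

// ---------------------------------------------------------------------------
// full-matrix Backward
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_backward(List prof, IntegerVector seq, bool local) {
  Prof P(prof);
  int m = P.m, n = seq.size();
  Specials sp(n);

  NumericMatrix M(m + 1, n + 1), I(m + 1, n + 1), D(m + 1, n + 1);
  std::fill(M.begin(), M.end(), NEG_INF);
  std::fill(I.begin(), I.end(), NEG_INF);
  std::fill(D.begin(), D.end(), NEG_INF);
  NumericVector sN(n + 1, NEG_INF), sB(n + 1, NEG_INF), sE(n + 1, NEG_INF),
      sC(n + 1, NEG_INF);
  double score;

  if (local) {
    sC[n] = sp.lnCT;
    for (int j = n - 1; j >= 0; --j) sC[j] = sC[j + 1] + sp.lnCC;
    for (int j = 0; j <= n; ++j) sE[j] = sC[j]; // E -> C with probability 1
    for (int i = m; i >= 1; --i) {
      for (int j = n; j >= 0; --j) {
        int c1 = (j < n) ? seq[j] - 1 : -1;
        double dM = NEG_INF, dI = NEG_INF, dD = NEG_INF;
        if (i < m && j < n)
          dM = P.msc(i + 1, c1) + M(i + 1, j + 1);
        if (j < n) dI = P.isc(i, c1) + I(i, j + 1);
        if (i < m) dD = D(i + 1, j);
        M(i, j) = lse4(P.tr(i, TMM) + dM, P.tr(i, TMI) + dI,
                       P.tr(i, TMD) + dD, sE[j]);
        I(i, j) = lse2(P.tr(i, TIM) + dM, P.tr(i, TII) + dI);
        D(i, j) = lse2(P.tr(i, TDM) + dM, P.tr(i, TDD) + dD);
      }
    }
    for (int j = n; j >= 0; --j) {
      double b = NEG_INF;
      if (j < n) {
        int c1 = seq[j] - 1;
        for (int i = 1; i <= m; ++i)
          b = lse2(b, P.entry[i] + P.msc(i, c1) + M(i, j + 1));
      }
      sB[j] = b;
      sN[j] = sB[j] + sp.lnNB;
      if (j < n) sN[j] = lse2(sN[j], sN[j + 1] + sp.lnNN);
    }
    score = sN[0];
  } else {
    M(m, n) = P.tr(m, TMM);
    I(m, n) = P.tr(m, TIM);
    D(m, n) = P.tr(m, TDM);
    for (int i = m; i >= 0; --i) {
      for (int j = n; j >= 0; --j) {
        if (i == m && j == n) continue;
        int c1 = (j < n) ? seq[j] - 1 : -1;
        double dM = NEG_INF, dI = NEG_INF, dD = NEG_INF;
        if (i < m && j < n)
          dM = P.msc(i + 1, c1) + M(i + 1, j + 1);
        if (j < n) dI = P.isc(i, c1) + I(i, j + 1);
        if (i < m) dD = D(i + 1, j);
        M(i, j) = lse3(P.tr(i, TMM) + dM, P.tr(i, TMI) + dI,
                       P.tr(i, TMD) + dD);
        I(i, j) = lse2(P.tr(i, TIM) + dM, P.tr(i, TII) + dI);
        D(i, j) = lse2(P.tr(i, TDM) + dM, P.tr(i, TDD) + dD);
      }
    }
    score = lse3(M(0, 0), I(0, 0), D(0, 0));
  }

  return List::create(
      _["score"] = score, _["M"] = M, _["I"] = I, _["D"] = D,
      _["specials"] = List::create(_["N"] = sN, _["B"] = sB, _["E"] = sE,
                                   _["C"] = sC));
}

// ---------------------------------------------------------------------------
// full-matrix Viterbi with traceback
// ---------------------------------------------------------------------------

// choice codes for traceback; ties resolved preferring M over D over I
enum { FROM_M = 1, FROM_I = 2, FROM_D = 3, FROM_B = 4, FROM_START = 5 };

// [[Rcpp::export]]
List cpp_viterbi(List prof, IntegerVector seq, bool local) {
  Prof P(prof);
  int m = P.m, n = seq.size();
  Specials sp(n);

  NumericMatrix M(m + 1, n + 1), I(m + 1, n + 1), D(m + 1, n + 1);
  std::fill(M.begin(), M.end(), NEG_INF);
  std::fill(I.begin(), I.end(), NEG_INF);
  std::fill(D.begin(), D.end(), NEG_INF);
  IntegerMatrix wM(m + 1, n + 1), wI(m + 1, n + 1), wD(m + 1, n + 1);
  NumericVector sB(n + 1, NEG_INF);

  if (local) {
    double nn = 0.0;
    for (int j = 0; j <= n; ++j) {
      sB[j] = nn + sp.lnNB;
      nn += sp.lnNN;
    }
  } else {
    M(0, 0) = I(0, 0) = D(0, 0) = 0.0;
    wM(0, 0) = wI(0, 0) = wD(0, 0) = FROM_START;
    for (int i = 1; i <= m; ++i) {
      double a = M(i - 1, 0) + P.tr(i - 1, TMD);
      double b = D(i - 1, 0) + P.tr(i - 1, TDD);
      D(i, 0) = (a >= b) ? a : b;
      wD(i, 0) = (a >= b) ? FROM_M : FROM_D;
    }
    for (int j = 1; j <= n; ++j) {
      int c = seq[j - 1] - 1;
      double a = M(0, j - 1) + P.tr(0, TMI);
      double b = I(0, j - 1) + P.tr(0, TII);
      I(0, j) = P.isc(0, c) + ((a >= b) ? a : b);
      wI(0, j) = (a >= b) ? FROM_M : FROM_I;
    }
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int c = seq[j - 1] - 1;
      // M: candidates in preference order M, D, I, B
      double cm = M(i - 1, j - 1) + P.tr(i - 1, TMM);
      double cd = D(i - 1, j - 1) + P.tr(i - 1, TDM);
      double ci = I(i - 1, j - 1) + P.tr(i - 1, TIM);
      double best = cm;
      int who = FROM_M;
      if (cd > best) { best = cd; who = FROM_D; }
      if (ci > best) { best = ci; who = FROM_I; }
      if (local) {
        double cb = sB[j - 1] + P.entry[i];
        if (cb > best) { best = cb; who = FROM_B; }
      }
      M(i, j) = P.msc(i, c) + best;
      wM(i, j) = who;

      double am = M(i, j - 1) + P.tr(i, TMI);
      double ai = I(i, j - 1) + P.tr(i, TII);
      I(i, j) = P.isc(i, c) + ((am >= ai) ? am : ai);
      wI(i, j) = (am >= ai) ? FROM_M : FROM_I;

      double bm = M(i - 1, j) + P.tr(i - 1, TMD);
      double bd = D(i - 1, j) + P.tr(i - 1, TDD);
      D(i, j) = (bm >= bd) ? bm : bd;
      wD(i, j) = (bm >= bd) ? FROM_M : FROM_D;
    }
  }

  double score;
  int ei = -1, ej = -1, estate = 1; // end cell/state of core traceback
  if (local) {
    // E(j) = max_i M(i,j); C chain; unihit so best single exit
    score = NEG_INF;
    for (int j = 1; j <= n; ++j) {
      for (int i = 1; i <= m; ++i) {
        double s = M(i, j) + (double)(n - j) * sp.lnCC + sp.lnCT;
        if (s > score) { score = s; ei = i; ej = j; }
      }
    }
    estate = 1;
  } else {
    double a = M(m, n) + P.tr(m, TMM);
    double b = I(m, n) + P.tr(m, TIM);
    double d = D(m, n) + P.tr(m, TDM);
    score = a; estate = 1; ei = m; ej = n;
    if (d > score) { score = d; estate = 3; }
    if (b > score) { score = b; estate = 2; }
  }

  // traceback through core states
  std::vector<int> st, pi, pj;
  if (ei >= 0 && score > NEG_INF) {
    int i = ei, j = ej, s = estate;
    while (true) {
      st.push_back(s); pi.push_back(i); pj.push_back(j);
      int w = (s == 1) ? wM(i, j) : (s == 2) ? wI(i, j) : wD(i, j);
      int ni = i, nj = j, ns;
      if (s == 1) { ni = i - 1; nj = j - 1; }
      else if (s == 2) { nj = j - 1; }
      else { ni = i - 1; }
      if (w == FROM_B || w == FROM_START) break;
      ns = (w == FROM_M) ? 1 : (w == FROM_I) ? 2 : 3;
      if (ni < 0 || nj < 0) break;
      i = ni; j = nj; s = ns;
    }
    std::reverse(st.begin(), st.end());
    std::reverse(pi.begin(), pi.end());
    std::reverse(pj.begin(), pj.end());
  }

  int L = st.size();
  IntegerMatrix path(L, 3);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = st[k];
    path(k, 1) = pi[k];
    path(k, 2) = pj[k];
  }
  return List::create(_["score"] = score, _["path"] = path);
}

// ---------------------------------------------------------------------------
// posterior-gain (maximum expected accuracy) alignment, full matrix
// gain: sum of match posteriors on diagonal steps plus ins_weight times
// insert posteriors on horizontal steps; delete steps gain 0
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_mea(NumericMatrix ppM, NumericMatrix ppI, double ins_weight) {
  int m = ppM.nrow() - 1, n = ppM.ncol() - 1;
  NumericMatrix AM(m + 1, n + 1), AI(m + 1, n + 1), AD(m + 1, n + 1);
  std::fill(AM.begin(), AM.end(), NEG_INF);
  std::fill(AI.begin(), AI.end(), NEG_INF);
  std::fill(AD.begin(), AD.end(), NEG_INF);
  IntegerMatrix wM(m + 1, n + 1), wI(m + 1, n + 1), wD(m + 1, n + 1);

  double best = NEG_INF;
  int bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // M cell: continue from M/D/I at (i-1,j-1) or start fresh
      double cm = AM(i - 1, j - 1), cd = AD(i - 1, j - 1),
             ci = AI(i - 1, j - 1);
      double b = 0.0; int who = FROM_START;
      if (cm > b) { b = cm; who = FROM_M; }
      if (cd > b) { b = cd; who = FROM_D; }
      if (ci > b) { b = ci; who = FROM_I; }
      AM(i, j) = ppM(i, j) + b;
      wM(i, j) = who;
      double am = AM(i, j - 1), ai = AI(i, j - 1);
      AI(i, j) = ins_weight * ppI(i, j) + ((am >= ai) ? am : ai);
      wI(i, j) = (am >= ai) ? FROM_M : FROM_I;
      double dm = AM(i - 1, j), dd = AD(i - 1, j);
      AD(i, j) = (dm >= dd) ? dm : dd;
      wD(i, j) = (dm >= dd) ? FROM_M : FROM_D;
      if (AM(i, j) > best) { best = AM(i, j); bi = i; bj = j; }
    }
  }

  std::vector<int> st, pi, pj;
  if (bi >= 1) {
    int i = bi, j = bj, s = 1;
    while (true) {
      st.push_back(s); pi.push_back(i); pj.push_back(j);
      int w = (s == 1) ? wM(i, j) : (s == 2) ? wI(i, j) : wD(i, j);
      if (s == 1) {
        if (w == FROM_START) break;
        i -= 1; j -= 1;
      } else if (s == 2) {
        j -= 1;
      } else {
        i -= 1;
      }
      s = (w == FROM_M) ? 1 : (w == FROM_I) ? 2 : (w == FROM_D) ? 3 : 1;
      if (i < 1 || j < 1) break;
    }
    std::reverse(st.begin(), st.end());
    std::reverse(pi.begin(), pi.end());
    std::reverse(pj.begin(), pj.end());
  }
  int L = st.size();
  IntegerMatrix path(L, 3);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = st[k]; path(k, 1) = pi[k]; path(k, 2) = pj[k];
  }
  double gain = (best == NEG_INF) ? 0.0 : best;
  return List::create(_["gain"] = gain, _["path"] = path);
}

// ---------------------------------------------------------------------------
// cloud search: seeded pruned anti-diagonal flood fill in 3-row storage
// ---------------------------------------------------------------------------

// interval retained after alpha/beta pruning; {1,0} (empty) if all pruned
static inline void prune_interval(const std::vector<double> &v, int lo,
                                  double maxd, double maxo, double alpha,
                                  double beta, int &keep_lo, int &keep_hi) {
  int L = v.size();
  int a = 0, b = L - 1;
  double thr_a = maxd - alpha, thr_b = maxo - beta;
  while (a < L && (v[a] < thr_a || v[a] < thr_b)) ++a;
  while (b >= a && (v[b] < thr_a || v[b] < thr_b)) --b;
  if (a > b) { keep_lo = 1; keep_hi = 0; return; }
  keep_lo = lo + a;
  keep_hi = lo + b;
}

// [[Rcpp::export]]
List cpp_cloud_search(List prof, IntegerVector seq, int ib, int jb, int ie,
                      int je, double alpha, double beta, int gamma,
                      bool debug) {
  Prof P(prof);
  int m = P.m, n = seq.size();

  // 3-row reusable cloud matrix: value of cell (i,j) lives at
  // row (i+j) mod 3, column j
  NumericMatrix cM(3, n + 1), cI(3, n + 1), cD(3, n + 1);
  std::fill(cM.begin(), cM.end(), NEG_INF);
  std::fill(cI.begin(), cI.end(), NEG_INF);
  std::fill(cD.begin(), cD.end(), NEG_INF);

  NumericMatrix dbg(debug ? m + 1 : 1, debug ? n + 1 : 1);
  if (debug) std::fill(dbg.begin(), dbg.end(), NEG_INF);

  std::vector<int> bd_d, bd_lo, bd_hi;
  int d0 = ib + jb;
  int dtarget = ie + je;
  cM(d0 % 3, jb) = 0.0;
  cI(d0 % 3, jb) = 0.0;
  cD(d0 % 3, jb) = 0.0;
  if (debug) dbg(ib, jb) = 0.0;
  bd_d.push_back(d0);
  bd_lo.push_back(ib);
  bd_hi.push_back(ib);

  double maxo = 0.0;
  double best_in = NA_REAL;
  bool have_best_in = false;
  if (d0 == dtarget) { best_in = maxo; have_best_in = true; }

  // retained i-intervals on the previous two anti-diagonals
  int a1 = ib, b1 = ib, a2 = 1, b2 = 0;
  bool have_prev2 = false;

  for (int d = d0 + 1;; ++d) {
    int lo = a1, hi = b1 + 1;
    if (have_prev2) { lo = std::min(lo, a2 + 1); hi = std::max(hi, b2 + 1); }
    lo = std::max(lo, std::max(ib, d - n));
    hi = std::min(hi, std::min(m, d - jb));
    if (lo > hi) break;
    if (d > m + n) break;

    int r = d % 3, r1 = (d - 1) % 3, r2 = (d - 2) % 3;

    std::vector<double> vals(hi - lo + 1, NEG_INF);
    for (int i = lo; i <= hi; ++i) {
      int j = d - i;
      int c = seq[j - 1] - 1;
      // reads gated on the retained intervals of d-1 / d-2
      bool p2 = have_prev2 && i - 1 >= a2 && i - 1 <= b2;
      double m11 = p2 ? cM(r2, j - 1) : NEG_INF;
      double i11 = p2 ? cI(r2, j - 1) : NEG_INF;
      double d11 = p2 ? cD(r2, j - 1) : NEG_INF;
      double m01 = (i >= a1 && i <= b1) ? cM(r1, j - 1) : NEG_INF;
      double i01 = (i >= a1 && i <= b1) ? cI(r1, j - 1) : NEG_INF;
      double m10 = (i - 1 >= a1 && i - 1 <= b1) ? cM(r1, j) : NEG_INF;
      double d10 = (i - 1 >= a1 && i - 1 <= b1) ? cD(r1, j) : NEG_INF;
      double vm = P.msc(i, c) + lse3(m11 + P.tr(i - 1, TMM),
                                     i11 + P.tr(i - 1, TIM),
                                     d11 + P.tr(i - 1, TDM));
      double vi = P.isc(i, c) + lse2(m01 + P.tr(i, TMI),
                                     i01 + P.tr(i, TII));
      double vd = lse2(m10 + P.tr(i - 1, TMD), d10 + P.tr(i - 1, TDD));
      cM(r, j) = vm;
      cI(r, j) = vi;
      cD(r, j) = vd;
      vals[i - lo] = vm;
      if (debug) dbg(i, j) = vm;
    }

    double maxd = NEG_INF;
    for (double v : vals) maxd = std::max(maxd, v);
    maxo = std::max(maxo, maxd);

    int klo = lo, khi = hi;
    if (hi - lo + 1 >= gamma)
      prune_interval(vals, lo, maxd, maxo, alpha, beta, klo, khi);
    if (klo > khi) break; // all pruned: flood fill stops

    bd_d.push_back(d);
    bd_lo.push_back(klo);
    bd_hi.push_back(khi);
    if (d == dtarget) { best_in = maxo; have_best_in = true; }

    a2 = a1; b2 = b1; have_prev2 = true;
    a1 = klo; b1 = khi;
  }

  if (!have_best_in) best_in = maxo; // pass stopped before the seed diagonal

  int nb = bd_d.size();
  IntegerMatrix bounds(nb, 3);
  for (int k = 0; k < nb; ++k) {
    bounds(k, 0) = bd_d[k];
    bounds(k, 1) = bd_lo[k];
    bounds(k, 2) = bd_hi[k];
  }
  List out = List::create(_["bounds"] = bounds, _["best"] = maxo,
                          _["best_in"] = best_in);
  if (debug) out["M"] = dbg;
  return out;
}

// ---------------------------------------------------------------------------
// sparse forward/backward over a flat-array layout
//
// layout fields (all 1-based row indices, 0-based flat offsets):
//   row0      : first layout row (may be a pure padding row)
//   nrow      : number of layout rows
//   row_off   : per-row column index of first allocated slot
//   row_len   : per-row number of allocated slots
//   blk_off   : per-row flat index of first allocated slot
//   left,right: per-row cloud run (right < left for padding-only rows)
//   total     : flat length
// ---------------------------------------------------------------------------

struct Layout {
  int row0, nrow, total;
  IntegerVector row_off, row_len, blk_off, left, right;
  Layout(List l)
      : row0(as<int>(l["row0"])), nrow(as<int>(l["nrow"])),
        total(as<int>(l["total"])), row_off(as<IntegerVector>(l["row_off"])),
        row_len(as<IntegerVector>(l["row_len"])),
        blk_off(as<IntegerVector>(l["blk_off"])),
        left(as<IntegerVector>(l["left"])),
        right(as<IntegerVector>(l["right"])) {}
  inline bool has_row(int i) const { return i >= row0 && i < row0 + nrow; }
  // flat index of (i,j), or -1 when outside the allocation
  inline int at(int i, int j) const {
    if (!has_row(i)) return -1;
    int r = i - row0;
    int c = j - row_off[r];
    if (c < 0 || c >= row_len[r]) return -1;
    return blk_off[r] + c;
  }
};

static inline double getf(const std::vector<double> &x, const Layout &L,
                          int i, int j) {
  int k = L.at(i, j);
  return (k < 0) ? NEG_INF : x[k];
}

// [[Rcpp::export]]
List cpp_sparse_forward(List prof, IntegerVector seq, List layout,
                        bool want_cells) {
  Prof P(prof);
  Layout L(layout);
  int n = seq.size();
  Specials sp(n);

  std::vector<double> M(L.total, NEG_INF), I(L.total, NEG_INF),
      D(L.total, NEG_INF);
  NumericVector sN(n + 1, NEG_INF), sB(n + 1, NEG_INF), sE(n + 1, NEG_INF),
      sC(n + 1, NEG_INF);
  sN[0] = 0.0;
  sB[0] = sp.lnNB;
  for (int j = 1; j <= n; ++j) {
    sN[j] = sN[j - 1] + sp.lnNN;
    sB[j] = sN[j] + sp.lnNB;
  }

  for (int r = 0; r < L.nrow; ++r) {
    int i = L.row0 + r;
    if (i < 1 || i > P.m) continue;
    for (int j = std::max(1, (int)L.left[r]); j <= L.right[r]; ++j) {
      int c = seq[j - 1] - 1;
      double mval = lse4(getf(M, L, i - 1, j - 1) + P.tr(i - 1, TMM),
                         getf(I, L, i - 1, j - 1) + P.tr(i - 1, TIM),
                         getf(D, L, i - 1, j - 1) + P.tr(i - 1, TDM),
                         sB[j - 1] + P.entry[i]);
      double iv = P.isc(i, c) + lse2(getf(M, L, i, j - 1) + P.tr(i, TMI),
                                     getf(I, L, i, j - 1) + P.tr(i, TII));
      double dv = lse2(getf(M, L, i - 1, j) + P.tr(i - 1, TMD),
                       getf(D, L, i - 1, j) + P.tr(i - 1, TDD));
      int k = L.at(i, j);
      M[k] = P.msc(i, c) + mval;
      I[k] = iv;
      D[k] = dv;
      sE[j] = lse2(sE[j], M[k]);
    }
  }
  for (int j = 1; j <= n; ++j) sC[j] = lse2(sC[j - 1] + sp.lnCC, sE[j]);
  double score = sC[n] + sp.lnCT;

  List out = List::create(
      _["score"] = score,
      _["specials"] = List::create(_["N"] = sN, _["B"] = sB, _["E"] = sE,
                                   _["C"] = sC));
  if (want_cells) {
    out["M"] = NumericVector(M.begin(), M.end());
    out["I"] = NumericVector(I.begin(), I.end());
    out["D"] = NumericVector(D.begin(), D.end());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_sparse_backward(List prof, IntegerVector seq, List layout,
                         bool want_cells) {
  Prof P(prof);
  Layout L(layout);
  int n = seq.size();
  Specials sp(n);

  std::vector<double> M(L.total, NEG_INF), I(L.total, NEG_INF),
      D(L.total, NEG_INF);
  NumericVector sN(n + 1, NEG_INF), sB(n + 1, NEG_INF), sE(n + 1, NEG_INF),
      sC(n + 1, NEG_INF);
  sC[n] = sp.lnCT;
  for (int j = n - 1; j >= 0; --j) sC[j] = sC[j + 1] + sp.lnCC;
  for (int j = 0; j <= n; ++j) sE[j] = sC[j];

  for (int r = L.nrow - 1; r >= 0; --r) {
    int i = L.row0 + r;
    if (i < 1 || i > P.m) continue;
    for (int j = L.right[r]; j >= std::max(1, (int)L.left[r]); --j) {
      int c1 = (j < n) ? seq[j] - 1 : 0;
      double dM = (i < P.m && j < n)
                      ? P.msc(i + 1, c1) + getf(M, L, i + 1, j + 1)
                      : NEG_INF;
      double dI = (j < n) ? P.isc(i, c1) + getf(I, L, i, j + 1) : NEG_INF;
      double dD = (i < P.m) ? getf(D, L, i + 1, j) : NEG_INF;
      int k = L.at(i, j);
      M[k] = lse4(P.tr(i, TMM) + dM, P.tr(i, TMI) + dI, P.tr(i, TMD) + dD,
                  sE[j]);
      I[k] = lse2(P.tr(i, TIM) + dM, P.tr(i, TII) + dI);
      D[k] = lse2(P.tr(i, TDM) + dM, P.tr(i, TDD) + dD);
      // accumulate B(j-1) <- entry_i + emission(i, t_j) + bM(i, j)
      sB[j - 1] = lse2(sB[j - 1],
                       P.entry[i] + P.msc(i, seq[j - 1] - 1) + M[k]);
    }
  }
  sN[n] = NEG_INF;
  for (int j = n - 1; j >= 0; --j)
    sN[j] = lse2(sB[j] + sp.lnNB, sN[j + 1] + sp.lnNN);
  double score = sN[0];

  List out = List::create(
      _["score"] = score,
      _["specials"] = List::create(_["N"] = sN, _["B"] = sB, _["E"] = sE,
                                   _["C"] = sC));
  if (want_cells) {
    out["M"] = NumericVector(M.begin(), M.end());
    out["I"] = NumericVector(I.begin(), I.end());
    out["D"] = NumericVector(D.begin(), D.end());
  }
  return out;
}

// posterior-gain alignment over the sparse layout
// [[Rcpp::export]]
List cpp_sparse_mea(NumericVector ppM, NumericVector ppI, List layout,
                    double ins_weight) {
  Layout L(layout);
  std::vector<double> AM(L.total, NEG_INF), AI(L.total, NEG_INF),
      AD(L.total, NEG_INF);
  std::vector<signed char> wM(L.total, 0), wI(L.total, 0), wD(L.total, 0);

  double best = NEG_INF;
  int bi = -1, bj = -1;
  for (int r = 0; r < L.nrow; ++r) {
    int i = L.row0 + r;
    for (int j = std::max(1, (int)L.left[r]); j <= L.right[r]; ++j) {
      int k = L.at(i, j);
      double cm = getf(AM, L, i - 1, j - 1), cd = getf(AD, L, i - 1, j - 1),
             ci = getf(AI, L, i - 1, j - 1);
      double b = 0.0; signed char who = FROM_START;
      if (cm > b) { b = cm; who = FROM_M; }
      if (cd > b) { b = cd; who = FROM_D; }
      if (ci > b) { b = ci; who = FROM_I; }
      AM[k] = ppM[k] + b;
      wM[k] = who;
      double am = getf(AM, L, i, j - 1), ai = getf(AI, L, i, j - 1);
      AI[k] = ins_weight * ppI[k] + ((am >= ai) ? am : ai);
      wI[k] = (am >= ai) ? FROM_M : FROM_I;
      double dm = getf(AM, L, i - 1, j), dd = getf(AD, L, i - 1, j);
      AD[k] = (dm >= dd) ? dm : dd;
      wD[k] = (dm >= dd) ? FROM_M : FROM_D;
      if (AM[k] > best) { best = AM[k]; bi = i; bj = j; }
    }
  }

  std::vector<int> st, pi, pj;
  if (bi >= 1) {
    int i = bi, j = bj, s = 1;
    while (true) {
      st.push_back(s); pi.push_back(i); pj.push_back(j);
      int k = L.at(i, j);
      int w = (s == 1) ? wM[k] : (s == 2) ? wI[k] : wD[k];
      if (s == 1) {
        if (w == FROM_START) break;
        i -= 1; j -= 1;
      } else if (s == 2) {
        j -= 1;
      } else {
        i -= 1;
      }
      s = (w == FROM_M) ? 1 : (w == FROM_I) ? 2 : (w == FROM_D) ? 3 : 1;
      if (i < 1 || j < 1 || L.at(i, j) < 0) break;
    }
    std::reverse(st.begin(), st.end());
    std::reverse(pi.begin(), pi.end());
    std::reverse(pj.begin(), pj.end());
  }
  int Lp = st.size();
  IntegerMatrix path(Lp, 3);
  for (int k = 0; k < Lp; ++k) {
    path(k, 0) = st[k]; path(k, 1) = pi[k]; path(k, 2) = pj[k];
  }
  return List::create(_["gain"] = (best == NEG_INF ? 0.0 : best),
                      _["path"] = path);
}

// ---------------------------------------------------------------------------
// batch scorers (rolling two-row storage) for calibration and null sims
// ---------------------------------------------------------------------------

static double forward_score_only(const Prof &P, const int *seq, int n) {
  Specials sp(n);
  int m = P.m;
  std::vector<double> Mp(n + 1, NEG_INF), Ip(n + 1, NEG_INF),
      Dp(n + 1, NEG_INF), Mc(n + 1, NEG_INF), Ic(n + 1, NEG_INF),
      Dc(n + 1, NEG_INF);
  std::vector<double> sB(n + 1), sE(n + 1, NEG_INF);
  double nn = 0.0;
  for (int j = 0; j <= n; ++j) { sB[j] = nn + sp.lnNB; nn += sp.lnNN; }

  for (int i = 1; i <= m; ++i) {
    Mc[0] = Ic[0] = Dc[0] = NEG_INF;
    for (int j = 1; j <= n; ++j) {
      int c = seq[j - 1] - 1;
      double mval = lse4(Mp[j - 1] + P.tr(i - 1, TMM),
                         Ip[j - 1] + P.tr(i - 1, TIM),
                         Dp[j - 1] + P.tr(i - 1, TDM),
                         sB[j - 1] + P.entry[i]);
      Mc[j] = P.msc(i, c) + mval;
      Ic[j] = P.isc(i, c) +
              lse2(Mc[j - 1] + P.tr(i, TMI), Ic[j - 1] + P.tr(i, TII));
      Dc[j] = lse2(Mp[j] + P.tr(i - 1, TMD), Dp[j] + P.tr(i - 1, TDD));
      sE[j] = lse2(sE[j], Mc[j]);
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
  }
  // C(j) = lse(C(j-1)+lnCC, E(j)), folded into a single accumulator
  double C = NEG_INF;
  for (int j = 1; j <= n; ++j) C = lse2(C + sp.lnCC, sE[j]);
  return C + sp.lnCT;
}

// [[Rcpp::export]]
NumericVector cpp_forward_score_batch(List prof, List seqs) {
  Prof P(prof);
  int N = seqs.size();
  NumericVector out(N);
  for (int s = 0; s < N; ++s) {
    IntegerVector q = seqs[s];
    out[s] = forward_score_only(P, q.begin(), q.size());
  }
  return out;
}

static double viterbi_score_only(const Prof &P, const int *seq, int n) {
  Specials sp(n);
  int m = P.m;
  std::vector<double> Mp(n + 1, NEG_INF), Ip(n + 1, NEG_INF),
      Dp(n + 1, NEG_INF), Mc(n + 1, NEG_INF), Ic(n + 1, NEG_INF),
      Dc(n + 1, NEG_INF);
  std::vector<double> sB(n + 1);
  double nn = 0.0;
  for (int j = 0; j <= n; ++j) { sB[j] = nn + sp.lnNB; nn += sp.lnNN; }
  double best = NEG_INF;
  for (int i = 1; i <= m; ++i) {
    Mc[0] = Ic[0] = Dc[0] = NEG_INF;
    for (int j = 1; j <= n; ++j) {
      int c = seq[j - 1] - 1;
      double v = std::max(std::max(Mp[j - 1] + P.tr(i - 1, TMM),
                                   Ip[j - 1] + P.tr(i - 1, TIM)),
                          std::max(Dp[j - 1] + P.tr(i - 1, TDM),
                                   sB[j - 1] + P.entry[i]));
      Mc[j] = P.msc(i, c) + v;
      Ic[j] = P.isc(i, c) +
              std::max(Mc[j - 1] + P.tr(i, TMI), Ic[j - 1] + P.tr(i, TII));
      Dc[j] = std::max(Mp[j] + P.tr(i - 1, TMD), Dp[j] + P.tr(i - 1, TDD));
      double s = Mc[j] + (double)(n - j) * sp.lnCC + sp.lnCT;
      if (s > best) best = s;
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_viterbi_score_batch(List prof, List seqs) {
  Prof P(prof);
  int N = seqs.size();
  NumericVector out(N);
  for (int s = 0; s < N; ++s) {
    IntegerVector q = seqs[s];
    out[s] = viterbi_score_only(P, q.begin(), q.size());
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sparse_forward_score_batch(List prof, List seqs,
                                             List layout) {
  int N = seqs.size();
  NumericVector out(N);
  for (int s = 0; s < N; ++s) {
    IntegerVector q = seqs[s];
    List r = cpp_sparse_forward(prof, q, layout, false);
    out[s] = as<double>(r["score"]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// banded gapped Viterbi around a diagonal (seed stage iii)
// band: cells with |(j - i) - diag| <= band are computed
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_banded_viterbi(List prof, IntegerVector seq, int diag, int band) {
  Prof P(prof);
  int m = P.m, n = seq.size();
  Specials sp(n);
  int w = 2 * band + 1;

  // per-row band storage, column j mapped to j - (i + diag - band)
  std::vector<double> Mp(w, NEG_INF), Ip(w, NEG_INF), Dp(w, NEG_INF),
      Mc(w, NEG_INF), Ic(w, NEG_INF), Dc(w, NEG_INF);
  std::vector<std::vector<signed char>> wM(m + 1), wI(m + 1), wD(m + 1);
  std::vector<double> sB(n + 1);
  double nn = 0.0;
  for (int j = 0; j <= n; ++j) { sB[j] = nn + sp.lnNB; nn += sp.lnNN; }

  double best = NEG_INF;
  int bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    wM[i].assign(w, 0); wI[i].assign(w, 0); wD[i].assign(w, 0);
    int base = i + diag - band;       // logical column of slot 0, row i
    int pbase = (i - 1) + diag - band;
    std::fill(Mc.begin(), Mc.end(), NEG_INF);
    std::fill(Ic.begin(), Ic.end(), NEG_INF);
    std::fill(Dc.begin(), Dc.end(), NEG_INF);
    for (int s = 0; s < w; ++s) {
      int j = base + s;
      if (j < 1 || j > n) continue;
      int c = seq[j - 1] - 1;
      auto pslot = [&](int jj) { return jj - pbase; };
      auto cslot = [&](int jj) { return jj - base; };
      auto getp = [&](std::vector<double> &x, int jj) {
        int t = pslot(jj);
        return (t >= 0 && t < w) ? x[t] : NEG_INF;
      };
      auto getc = [&](std::vector<double> &x, int jj) {
        int t = cslot(jj);
        return (t >= 0 && t < w) ? x[t] : NEG_INF;
      };
      double cm = getp(Mp, j - 1) + P.tr(i - 1, TMM);
      double cd = getp(Dp, j - 1) + P.tr(i - 1, TDM);
      double ci = getp(Ip, j - 1) + P.tr(i - 1, TIM);
      double cb = sB[j - 1] + P.entry[i];
      double v = cm; signed char who = FROM_M;
      if (cd > v) { v = cd; who = FROM_D; }
      if (ci > v) { v = ci; who = FROM_I; }
      if (cb > v) { v = cb; who = FROM_B; }
      Mc[s] = P.msc(i, c) + v;
      wM[i][s] = who;
      double am = getc(Mc, j - 1) + P.tr(i, TMI);
      double ai = getc(Ic, j - 1) + P.tr(i, TII);
      Ic[s] = P.isc(i, c) + ((am >= ai) ? am : ai);
      wI[i][s] = (am >= ai) ? FROM_M : FROM_I;
      double dm = getp(Mp, j) + P.tr(i - 1, TMD);
      double dd = getp(Dp, j) + P.tr(i - 1, TDD);
      Dc[s] = (dm >= dd) ? dm : dd;
      wD[i][s] = (dm >= dd) ? FROM_M : FROM_D;
      double sc = Mc[s] + (double)(n - j) * sp.lnCC + sp.lnCT;
      if (sc > best) { best = sc; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
  }

  int qb = NA_INTEGER, qe = NA_INTEGER, tb = NA_INTEGER, te = NA_INTEGER;
  if (bi > 0) {
    // traceback within the band to recover the begin cell
    int i = bi, j = bj, s = 1;
    qe = bi; te = bj;
    while (true) {
      int slot = j - (i + diag - band);
      if (slot < 0 || slot >= w || i < 1 || j < 1) break;
      int ww = (s == 1) ? wM[i][slot] : (s == 2) ? wI[i][slot] : wD[i][slot];
      if (s == 1) { qb = i; tb = j; }
      if (s == 1 && ww == FROM_B) break;
      if (s == 1) { i -= 1; j -= 1; }
      else if (s == 2) { j -= 1; }
      else { i -= 1; }
      s = (ww == FROM_M) ? 1 : (ww == FROM_I) ? 2 : 3;
    }
  }
  return List::create(_["score"] = best, _["qstart"] = qb, _["qend"] = qe,
                      _["tstart"] = tb, _["tend"] = te);
}
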