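#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Local-alignment DP for profile HMM log-odds scoring (log2 domain).
// Path space: uniform entry over ordered match-state pairs (k1 <= k2) with
// weight 2/(K*(K+1)) folded into `lentry`; the core walk uses node
// transitions M->M/I/D, I->M/I, D->M/D; exit after any match state is free.
// Emission matrices already hold log2(e/background); -Inf masks a position.

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b, d = std::fabs(a - b);
  return m + std::log1p(std::exp2(-d)) / M_LN2;
}

// [[Rcpp::export(name = ".fwd_logodds")]]
double fwd_logodds(NumericMatrix lm, NumericMatrix li,
                   NumericVector tMM, NumericVector tMI, NumericVector tMD,
                   NumericVector tIM, NumericVector tII,
                   NumericVector tDM, NumericVector tDD,
                   double lentry) {
  int K = lm.nrow(), L = lm.ncol();
  NumericMatrix M(K, L), I(K, L), D(K, L);
  std::fill(M.begin(), M.end(), R_NegInf);
  std::fill(I.begin(), I.end(), R_NegInf);
  std::fill(D.begin(), D.end(), R_NegInf);
  double total = R_NegInf;
  // D(k, i): in state D_k with residue i the last one consumed; filled after
  // the M/I sweep of column i since D_k can follow M_{k-1} emitting x_i.
  for (int i = 0; i < L; ++i) {
    for (int k = 0; k < K; ++k) {
      double m = lentry;  // fresh local entry at (k, i)
      if (k > 0 && i > 0) {
        m = lse2(m, M(k - 1, i - 1) + tMM[k - 1]);
        m = lse2(m, I(k - 1, i - 1) + tIM[k - 1]);
        m = lse2(m, D(k - 1, i - 1) + tDM[k - 1]);
      }
      M(k, i) = lm(k, i) + m;
      double ins = R_NegInf;
      if (i > 0 && k < K - 1) {
        ins = lse2(M(k, i - 1) + tMI[k], I(k, i - 1) + tII[k]);
      }
      I(k, i) = (k < K - 1) ? li(k, i) + ins : R_NegInf;
      total = lse2(total, M(k, i));
    }
    for (int k = 1; k < K; ++k) {
      D(k, i) = lse2(M(k - 1, i) + tMD[k - 1], D(k - 1, i) + tDD[k - 1]);
    }
  }
  return total;
}

// [[Rcpp::export(name = ".vit_logodds")]]
List vit_logodds(NumericMatrix lm, NumericMatrix li,
                 NumericVector tMM, NumericVector tMI, NumericVector tMD,
                 NumericVector tIM, NumericVector tII,
                 NumericVector tDM, NumericVector tDD,
                 double lentry) {
  int K = lm.nrow(), L = lm.ncol();
  NumericMatrix M(K, L), I(K, L), D(K, L);
  std::fill(M.begin(), M.end(), R_NegInf);
  std::fill(I.begin(), I.end(), R_NegInf);
  std::fill(D.begin(), D.end(), R_NegInf);
  // back-pointers: 0 = entry, 1 = from M, 2 = from I, 3 = from D
  IntegerMatrix bM(K, L), bI(K, L), bD(K, L);
  double best = R_NegInf;
  int bk = -1, bi = -1;
  for (int i = 0; i < L; ++i) {
    for (int k = 0; k < K; ++k) {
      double m = lentry;
      int bp = 0;
      if (k > 0 && i > 0) {
        double vm = M(k - 1, i - 1) + tMM[k - 1];
        double vi = I(k - 1, i - 1) + tIM[k - 1];
        double vd = D(k - 1, i - 1) + tDM[k - 1];
        if (vm > m) { m = vm; bp = 1; }
        if (vi > m) { m = vi; bp = 2; }
        if (vd > m) { m = vd; bp = 3; }
      }
      M(k, i) = lm(k, i) + m;
      bM(k, i) = bp;
      double ins = R_NegInf;
      int bpi = 1;
      if (i > 0 && k < K - 1) {
        double vm = M(k, i - 1) + tMI[k];
        double vi = I(k, i - 1) + tII[k];
        ins = vm; bpi = 1;
        if (vi > ins) { ins = vi; bpi = 2; }
      }
      I(k, i) = (k < K - 1) ? li(k, i) + ins : R_NegInf;
      bI(k, i) = bpi;
      if (M(k, i) > best) { best = M(k, i); bk = k; bi = i; }
    }
    for (int k = 1; k < K; ++k) {
      double vm = M(k - 1, i) + tMD[k - 1];
      double vd = D(k - 1, i) + tDD[k - 1];
      if (vm >= vd) { D(k, i) = vm; bD(k, i) = 1; }
      else          { D(k, i) = vd; bD(k, i) = 3; }
    }
  }
  if (!R_finite(best)) {
    return List::create(_["score"] = best, _["states"] = IntegerVector(0),
                        _["nodes"] = IntegerVector(0), _["pos"] = IntegerVector(0));
  }
  // traceback from M(bk, bi)
  std::vector<int> st, nd, ps;  // state 1=M,2=I,3=D ; node 1-based ; pos 1-based (0 for D)
  int state = 1, k = bk, i = bi;
  while (true) {
    st.push_back(state); nd.push_back(k + 1);
    ps.push_back(state == 3 ? 0 : i + 1);
    int bp;
    if (state == 1) bp = bM(k, i);
    else if (state == 2) bp = bI(k, i);
    else bp = bD(k, i);
    if (state == 1) {
      if (bp == 0) break;
      state = bp; --k; --i;
    } else if (state == 2) {
      state = bp; --i;
    } else {  // D: predecessor at same i
      state = bp; --k;
    }
  }
  std::reverse(st.begin(), st.end());
  std::reverse(nd.begin(), nd.end());
  std::reverse(ps.begin(), ps.end());
  return List::create(_["score"] = best,
                      _["states"] = IntegerVector(st.begin(), st.end()),
                      _["nodes"] = IntegerVector(nd.begin(), nd.end()),
                      _["pos"] = IntegerVector(ps.begin(), ps.end()));
}
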