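#include <Rcpp.h>
using namespace Rcpp;

// Minimum free energy of an ungapped antiparallel two-strand complex.
//
// Sequences are 0-based codes (A=0, C=1, G=2, T=3), both 5'->3'. For every
// register of b against a and every window whose terminal columns are
// Watson-Crick pairs, the window free energy is
//   dG = dH - T * dS / 1000
// with dH/dS summed over nearest-neighbour stacks (16x16 lookup, zero for
// unparameterised tandem-mismatch stacks), duplex initiation, terminal A.T
// penalties and an entropic monovalent-salt term per stack. Unpaired
// overhangs are treated as neutral. The reported MFE is the minimum over
// all registers/windows, clamped at 0 (unbound reference state).

static inline bool is_wc(int top, int bot) { return bot == 3 - top; }
static inline bool is_at(int top, int bot) {
  return (top == 0 && bot == 3) || (top == 3 && bot == 0);
}

static double mfe_pair(const int* a, int la, const int* b, int lb,
                       const double* dH, const double* dS,
                       double tempK, double salt_dS,
                       double initH, double initS,
                       double termH, double termS) {
  double best = 0.0;
  for (int s = -(lb - 1); s <= la - 1; ++s) {
    int i0 = s > 0 ? s : 0;
    int i1 = (s + lb - 1) < (la - 1) ? (s + lb - 1) : (la - 1);
    int w = i1 - i0 + 1;
    if (w < 2) continue;
    // column pair codes; bottom strand is read 3'->5' against a
    // (b reversed), column i pairs a[i] with b[lb - 1 - (i - s)]
    std::vector<int> top(w), bot(w);
    for (int i = i0; i <= i1; ++i) {
      top[i - i0] = a[i];
      bot[i - i0] = b[lb - 1 - (i - s)];
    }
    // prefix sums of stack energies
    std::vector<double> ch(w, 0.0), cs(w, 0.0);
    for (int k = 1; k < w; ++k) {
      int idx = (4 * top[k - 1] + bot[k - 1]) * 16 + (4 * top[k] + bot[k]);
      ch[k] = ch[k - 1] + dH[idx];
      cs[k] = cs[k - 1] + dS[idx];
    }
    for (int i = 0; i < w - 1; ++i) {
      if (!is_wc(top[i], bot[i])) continue;
      double endH_i = termH * (is_at(top[i], bot[i]) ? 1.0 : 0.0);
      double endS_i = termS * (is_at(top[i], bot[i]) ? 1.0 : 0.0);
      for (int j = i + 1; j < w; ++j) {
        if (!is_wc(top[j], bot[j])) continue;
        double h = initH + endH_i + (ch[j] - ch[i]) +
                   termH * (is_at(top[j], bot[j]) ? 1.0 : 0.0);
        double sS = initS + endS_i + (cs[j] - cs[i]) +
                    termS * (is_at(top[j], bot[j]) ? 1.0 : 0.0) +
                    salt_dS * (j - i);
        double g = h - tempK * sS / 1000.0;
        if (g < best) best = g;
      }
    }
  }
  return best;
}

// [[Rcpp::export(name = ".mfe_duplex_cpp")]]
double mfe_duplex_cpp(IntegerVector a, IntegerVector b,
                      NumericMatrix dH, NumericMatrix dS,
                      double tempK, double salt_dS,
                      NumericVector init, NumericVector term_at) {
  // flatten lookup row-major by (p1 * 16 + p2); matrices are 16x16 with
  // 1-based pair codes in R, here converted to 0-based
  std::vector<double> fH(256), fS(256);
  for (int i = 0; i < 16; ++i)
    for (int j = 0; j < 16; ++j) {
      fH[i * 16 + j] = dH(i, j);
      fS[i * 16 + j] = dS(i, j);
    }
  return mfe_pair(INTEGER(a), a.size(), INTEGER(b), b.size(),
                  fH.data(), fS.data(), tempK, salt_dS,
                  init[0], init[1], term_at[0], term_at[1]);
}

// [[Rcpp::export(name = ".mfe_matrix_cpp")]]
NumericMatrix mfe_matrix_cpp(IntegerMatrix fwd, IntegerMatrix rev,
                             NumericMatrix dH, NumericMatrix dS,
                             double tempK, double salt_dS,
                             NumericVector init, NumericVector term_at) {
  int n = fwd.nrow(), m = rev.nrow();
  int la = fwd.ncol(), lb = rev.ncol();
  std::vector<double> fH(256), fS(256);
  for (int i = 0; i < 16; ++i)
    for (int j = 0; j < 16; ++j) {
      fH[i * 16 + j] = dH(i, j);
      fS[i * 16 + j] = dS(i, j);
    }
  NumericMatrix out(n, m);
  std::vector<int> arow(la), brow(lb);
  for (int x = 0; x < n; ++x) {
    for (int k = 0; k < la; ++k) arow[k] = fwd(x, k);
    for (int y = 0; y < m; ++y) {
      for (int k = 0; k < lb; ++k) brow[k] = rev(y, k);
      out(x, y) = mfe_pair(arow.data(), la, brow.data(), lb,
                           fH.data(), fS.data(), tempK, salt_dS,
                           init[0], init[1], term_at[0], term_at[1]);
    }
  }
  return out;
}
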