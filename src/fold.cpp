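// Minimum-free-energy folding of short RNA windows under a simplified
// Zuker-style nearest-neighbor model: Watson-Crick + GU wobble pairs,
// stacking free energies, size-dependent hairpin/bulge/interior penalties
// (interior loops capped at `max_interior` unpaired bases), and an affine
// multiloop term. External loop bases are free, so the open chain scores 0
// and the MFE is always <= 0. Pseudoknots are not considered.
//
// Base codes: A=0, C=1, G=2, U/T=3, N=4 (never pairs).
// Pair types: 0 none, 1 AU, 2 UA, 3 CG, 4 GC, 5 GU, 6 UG.

#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

static const double INF = 1e9;

static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 3 && b == 0) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 1) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

struct FoldCtx {
  const std::vector<int>& s;
  const NumericMatrix& stack_dg;     // 6x6, [outer-1, inner-1]
  const NumericVector& hairpin_dg;   // 1-indexed by loop size
  const NumericVector& bulge_dg;
  const NumericVector& internal_dg;
  double ml_a, ml_b, ml_c;
  int min_hairpin, max_interior;
  int n;
  std::vector<double> V, WM, W2;     // V,WM are n*n; W2 length n+1
  FoldCtx(const std::vector<int>& s_, const NumericMatrix& st,
          const NumericVector& hp, const NumericVector& bl,
          const NumericVector& il, double a, double b, double c,
          int mh, int mi)
    : s(s_), stack_dg(st), hairpin_dg(hp), bulge_dg(bl), internal_dg(il),
      ml_a(a), ml_b(b), ml_c(c), min_hairpin(mh), max_interior(mi),
      n((int)s_.size()),
      V(std::vector<double>((size_t)n * n, INF)),
      WM(std::vector<double>((size_t)n * n, INF)),
      W2(std::vector<double>(n + 1, 0.0)) {}
  inline double loop_size(const NumericVector& v, int sz) const {
    if (sz < 1 || sz > v.size()) return INF;
    return v[sz - 1];
  }
  // energy of the loop closed by pair (i,j) with inner helix (k,l)
  inline double two_loop(int i, int j, int k, int l) const {
    int s1 = k - i - 1, s2 = j - l - 1;
    if (s1 + s2 > max_interior) return INF;
    if (s1 == 0 && s2 == 0) {
      int po = pair_type(s[i], s[j]), pi = pair_type(s[k], s[l]);
      return stack_dg(po - 1, pi - 1);
    }
    if (s1 == 0 || s2 == 0) return loop_size(bulge_dg, s1 + s2);
    return loop_size(internal_dg, s1 + s2);
  }
  inline double v(int i, int j) const { return V[(size_t)i * n + j]; }
  inline double wm(int i, int j) const {
    if (i > j) return INF;
    return WM[(size_t)i * n + j];
  }
};

static void fill_tables(FoldCtx& c) {
  int n = c.n;
  // V and WM interleaved by increasing span: V(i,j)'s multiloop case reads
  // WM over strictly shorter spans, WM(i,j) reads V(i,j) of the same cell.
  for (int span = 0; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // --- V(i,j): i pairs j ---
      if (span >= c.min_hairpin + 1 && pair_type(c.s[i], c.s[j]) != 0) {
        double best = c.loop_size(c.hairpin_dg, j - i - 1);  // hairpin
        // stack / bulge / interior
        int kmax = std::min(j - c.min_hairpin - 1, i + c.max_interior + 1);
        for (int k = i + 1; k <= kmax; ++k) {
          int lmin = std::max(k + c.min_hairpin + 1,
                              j - 1 - (c.max_interior - (k - i - 1)));
          for (int l = j - 1; l >= lmin; --l) {
            if (pair_type(c.s[k], c.s[l]) == 0) continue;
            double vv = c.v(k, l);
            if (vv >= INF) continue;
            double e = c.two_loop(i, j, k, l) + vv;
            if (e < best) best = e;
          }
        }
        // multiloop closing: a + b(closing branch) + WM(i+1,k) + WM(k+1,j-1)
        for (int k = i + 1; k < j - 1; ++k) {
          double e1 = c.wm(i + 1, k), e2 = c.wm(k + 1, j - 1);
          if (e1 >= INF || e2 >= INF) continue;
          double e = c.ml_a + c.ml_b + e1 + e2;
          if (e < best) best = e;
        }
        c.V[(size_t)i * n + j] = best;
      }
      // --- WM(i,j): multiloop segment with >= 1 branch ---
      double best = INF;
      double vv = c.v(i, j);
      if (vv < INF) best = vv + c.ml_b;
      if (i + 1 <= j) {
        double e = c.wm(i + 1, j);
        if (e < INF && e + c.ml_c < best) best = e + c.ml_c;
        e = c.wm(i, j - 1);
        if (e < INF && e + c.ml_c < best) best = e + c.ml_c;
      }
      for (int k = i; k < j; ++k) {
        double e1 = c.wm(i, k), e2 = c.wm(k + 1, j);
        if (e1 >= INF || e2 >= INF) continue;
        if (e1 + e2 < best) best = e1 + e2;
      }
      c.WM[(size_t)i * n + j] = best;
    }
  }
  // suffix external array: W2[i] = MFE of region i..n-1, W2[n] = 0
  c.W2[n] = 0.0;
  for (int i = n - 1; i >= 0; --i) {
    double best = c.W2[i + 1];
    for (int j = i + c.min_hairpin + 1; j < n; ++j) {
      double vv = c.v(i, j);
      if (vv >= INF) continue;
      double e = vv + c.W2[j + 1];
      if (e < best) best = e;
    }
    c.W2[i] = best;
  }
}

static const double EPS = 1e-9;

static void trace_v(FoldCtx& c, int i, int j, std::string& db);
static void trace_wm(FoldCtx& c, int i, int j, std::string& db);

static void trace_v(FoldCtx& c, int i, int j, std::string& db) {
  db[i] = '('; db[j] = ')';
  double target = c.v(i, j);
  // hairpin
  if (std::abs(target - c.loop_size(c.hairpin_dg, j - i - 1)) < EPS) return;
  // stack / bulge / interior, smallest k first then largest l (stack first)
  int kmax = std::min(j - c.min_hairpin - 1, i + c.max_interior + 1);
  for (int k = i + 1; k <= kmax; ++k) {
    int lmin = std::max(k + c.min_hairpin + 1,
                        j - 1 - (c.max_interior - (k - i - 1)));
    for (int l = j - 1; l >= lmin; --l) {
      if (pair_type(c.s[k], c.s[l]) == 0) continue;
      double vv = c.v(k, l);
      if (vv >= INF) continue;
      if (std::abs(target - (c.two_loop(i, j, k, l) + vv)) < EPS) {
        trace_v(c, k, l, db);
        return;
      }
    }
  }
  // multiloop
  for (int k = i + 1; k < j - 1; ++k) {
    double e1 = c.wm(i + 1, k), e2 = c.wm(k + 1, j - 1);
    if (e1 >= INF || e2 >= INF) continue;
    if (std::abs(target - (c.ml_a + c.ml_b + e1 + e2)) < EPS) {
      trace_wm(c, i + 1, k, db);
      trace_wm(c, k + 1, j - 1, db);
      return;
    }
  }
  Rcpp::stop("internal error: V traceback failed");
}

static void trace_wm(FoldCtx& c, int i, int j, std::string& db) {
  double target = c.wm(i, j);
  double vv = c.v(i, j);
  if (vv < INF && std::abs(target - (vv + c.ml_b)) < EPS) {
    trace_v(c, i, j, db);
    return;
  }
  if (i + 1 <= j) {
    double e = c.wm(i + 1, j);
    if (e < INF && std::abs(target - (e + c.ml_c)) < EPS) {
      trace_wm(c, i + 1, j, db);
      return;
    }
    e = c.wm(i, j - 1);
    if (e < INF && std::abs(target - (e + c.ml_c)) < EPS) {
      trace_wm(c, i, j - 1, db);
      return;
    }
  }
  for (int k = i; k < j; ++k) {
    double e1 = c.wm(i, k), e2 = c.wm(k + 1, j);
    if (e1 >= INF || e2 >= INF) continue;
    if (std::abs(target - (e1 + e2)) < EPS) {
      trace_wm(c, i, k, db);
      trace_wm(c, k + 1, j, db);
      return;
    }
  }
  Rcpp::stop("internal error: WM traceback failed");
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector seq_codes, NumericMatrix stack_dg,
                  NumericVector hairpin_dg, NumericVector bulge_dg,
                  NumericVector internal_dg, double ml_a, double ml_b,
                  double ml_c, int min_hairpin, int max_interior) {
  std::vector<int> s(seq_codes.begin(), seq_codes.end());
  int n = (int)s.size();
  std::string db(n, '.');
  if (n < min_hairpin + 2) {
    return List::create(_["mfe"] = 0.0, _["structure"] = db);
  }
  FoldCtx c(s, stack_dg, hairpin_dg, bulge_dg, internal_dg,
            ml_a, ml_b, ml_c, min_hairpin, max_interior);
  fill_tables(c);
  double mfe = c.W2[0];
  // external traceback left-to-right, preferring a pair at the earliest
  // opening index among co-optimal choices
  int i = 0;
  while (i < n) {
    bool paired = false;
    for (int j = i + c.min_hairpin + 1; j < n; ++j) {
      double vv = c.v(i, j);
      if (vv >= INF) continue;
      if (std::abs(c.W2[i] - (vv + c.W2[j + 1])) < EPS) {
        trace_v(c, i, j, db);
        i = j + 1;
        paired = true;
        break;
      }
    }
    if (!paired) i += 1;
  }
  if (mfe > 0) mfe = 0.0;  // defensive; cannot happen by construction
  return List::create(_["mfe"] = mfe, _["structure"] = db);
}

// Nussinov-style maximum number of nested pairs (sanity bound)
// [[Rcpp::export(name = ".nussinov_cpp")]]
int nussinov_cpp(IntegerVector seq_codes, int min_loop) {
  std::vector<int> s(seq_codes.begin(), seq_codes.end());
  int n = (int)s.size();
  if (n < min_loop + 2) return 0;
  std::vector<int> M((size_t)n * n, 0);
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[(size_t)i * n + (j - 1)];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (pair_type(s[k], s[j]) == 0) continue;
        int left = (k > i) ? M[(size_t)i * n + (k - 1)] : 0;
        int inner = (k + 1 <= j - 1) ? M[(size_t)(k + 1) * n + (j - 1)] : 0;
        int e = left + inner + 1;
        if (e > best) best = e;
      }
      M[(size_t)i * n + j] = best;
    }
  }
  return M[(size_t)0 * n + (n - 1)];
}
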