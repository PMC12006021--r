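#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Gotoh affine-gap pairwise alignment.
//
// A gap of length g costs open + extend * (g - 1): the first gapped column
// pays `open`, each further column of the same run pays `extend`.
// Three DP states per cell: M (residue-residue column), X (gap in the
// subject, consumes query = "up"), Y (gap in the query, consumes subject =
// "left"). Traceback ties break diagonal > up > left (M > X > Y), so
// results are deterministic.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct DP {
  int m, n;
  std::vector<double> M, X, Y;
  DP(int m_, int n_) : m(m_), n(n_),
    M((size_t)(m_ + 1) * (n_ + 1), NEG_INF),
    X((size_t)(m_ + 1) * (n_ + 1), NEG_INF),
    Y((size_t)(m_ + 1) * (n_ + 1), NEG_INF) {}
  inline size_t idx(int i, int j) const { return (size_t)i * (n + 1) + j; }
};

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

// state codes: 0 = M, 1 = X (up), 2 = Y (left); ties prefer M > X > Y
static int pick_state(double vm, double vx, double vy) {
  double best = max3(vm, vx, vy);
  if (vm == best) return 0;
  if (vx == best) return 1;
  return 2;
}

static void fill_global(DP &dp, const IntegerVector &q, const IntegerVector &s,
                        const NumericMatrix &sub, double go, double ge) {
  int m = dp.m, n = dp.n;
  dp.M[dp.idx(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i)
    dp.X[dp.idx(i, 0)] = (i == 1) ? -go : dp.X[dp.idx(i - 1, 0)] - ge;
  for (int j = 1; j <= n; ++j)
    dp.Y[dp.idx(0, j)] = (j == 1) ? -go : dp.Y[dp.idx(0, j - 1)] - ge;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      size_t ij = dp.idx(i, j), d = dp.idx(i - 1, j - 1),
             u = dp.idx(i - 1, j), l = dp.idx(i, j - 1);
      dp.M[ij] = sub(q[i - 1], s[j - 1]) + max3(dp.M[d], dp.X[d], dp.Y[d]);
      dp.X[ij] = max3(dp.M[u] - go, dp.X[u] - ge, dp.Y[u] - go);
      dp.Y[ij] = max3(dp.M[l] - go, dp.X[l] - go, dp.Y[l] - ge);
    }
  }
}

static void fill_local(DP &dp, const IntegerVector &q, const IntegerVector &s,
                       const NumericMatrix &sub, double go, double ge) {
  int m = dp.m, n = dp.n;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      size_t ij = dp.idx(i, j), d = dp.idx(i - 1, j - 1),
             u = dp.idx(i - 1, j), l = dp.idx(i, j - 1);
      double prev = max3(dp.M[d], dp.X[d], dp.Y[d]);
      if (prev < 0.0) prev = 0.0; // fresh start (also covers NEG_INF borders)
      dp.M[ij] = std::max(0.0, sub(q[i - 1], s[j - 1]) + prev);
      dp.X[ij] = max3(dp.M[u] - go, dp.X[u] - ge, dp.Y[u] - go);
      dp.Y[ij] = max3(dp.M[l] - go, dp.X[l] - go, dp.Y[l] - ge);
    }
  }
}

// [[Rcpp::export]]
List align_pair_cpp(IntegerVector q, IntegerVector s, NumericMatrix sub,
                    double gap_open, double gap_extend, bool local) {
  int m = q.size(), n = s.size();
  DP dp(m, n);
  if (local) fill_local(dp, q, s, sub, gap_open, gap_extend);
  else fill_global(dp, q, s, sub, gap_open, gap_extend);

  int i, j, state;
  double score;
  if (local) {
    score = 0.0; i = 0; j = 0; state = 0;
    for (int ii = 1; ii <= m; ++ii)
      for (int jj = 1; jj <= n; ++jj)
        if (dp.M[dp.idx(ii, jj)] > score) { score = dp.M[dp.idx(ii, jj)]; i = ii; j = jj; }
    if (score <= 0.0)
      return List::create(_["score"] = 0.0, _["q_aln"] = IntegerVector(0),
                          _["s_aln"] = IntegerVector(0),
                          _["q_start"] = NA_INTEGER, _["q_end"] = NA_INTEGER,
                          _["s_start"] = NA_INTEGER, _["s_end"] = NA_INTEGER);
  } else {
    size_t e = dp.idx(m, n);
    score = max3(dp.M[e], dp.X[e], dp.Y[e]);
    state = pick_state(dp.M[e], dp.X[e], dp.Y[e]);
    i = m; j = n;
  }
  int q_end = i, s_end = j;

  // aligned columns, built in reverse; 0-based residue codes, -1 = gap
  std::vector<int> qa, sa;
  while (true) {
    if (!local && i == 0 && j == 0) break;
    if (state == 0) {
      size_t d = dp.idx(i - 1, j - 1);
      qa.push_back(q[i - 1]); sa.push_back(s[j - 1]);
      double prev = max3(dp.M[d], dp.X[d], dp.Y[d]);
      --i; --j;
      if (local && prev <= 0.0) break; // local alignment started at this cell
      if (!local && i == 0 && j == 0) break;
      state = pick_state(dp.M[d], dp.X[d], dp.Y[d]);
    } else if (state == 1) {
      size_t u = dp.idx(i - 1, j);
      qa.push_back(q[i - 1]); sa.push_back(-1);
      state = pick_state(dp.M[u] - gap_open, dp.X[u] - gap_extend,
                         dp.Y[u] - gap_open);
      --i;
    } else {
      size_t l = dp.idx(i, j - 1);
      qa.push_back(-1); sa.push_back(s[j - 1]);
      state = pick_state(dp.M[l] - gap_open, dp.X[l] - gap_open,
                         dp.Y[l] - gap_extend);
      --j;
    }
  }

  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  return List::create(_["score"] = score,
                      _["q_aln"] = IntegerVector(qa.begin(), qa.end()),
                      _["s_aln"] = IntegerVector(sa.begin(), sa.end()),
                      _["q_start"] = local ? i + 1 : 1,
                      _["q_end"] = local ? q_end : m,
                      _["s_start"] = local ? j + 1 : 1,
                      _["s_end"] = local ? s_end : n);
}

// Score-only batch variant (rolling rows); used by the screening stage and
// by large property tests where no traceback is needed.
// [[Rcpp::export]]
NumericVector score_pairs_cpp(List qs, List ss, NumericMatrix sub,
                              double gap_open, double gap_extend, bool local) {
  int np = qs.size();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    IntegerVector q = qs[p], s = ss[p];
    int m = q.size(), n = s.size();
    std::vector<double> Mp(n + 1, NEG_INF), Xp(n + 1, NEG_INF), Yp(n + 1, NEG_INF),
                        Mc(n + 1), Xc(n + 1), Yc(n + 1);
    double best = 0.0;
    if (!local) {
      Mp[0] = 0.0;
      for (int j = 1; j <= n; ++j) Yp[j] = (j == 1) ? -gap_open : Yp[j - 1] - gap_extend;
    }
    for (int i = 1; i <= m; ++i) {
      Mc[0] = NEG_INF; Yc[0] = NEG_INF;
      if (local) Xc[0] = NEG_INF;
      else Xc[0] = (i == 1) ? -gap_open : Xp[0] - gap_extend;
      for (int j = 1; j <= n; ++j) {
        double sc = sub(q[i - 1], s[j - 1]);
        double dprev = max3(Mp[j - 1], Xp[j - 1], Yp[j - 1]);
        if (local) {
          if (dprev < 0.0) dprev = 0.0;
          Mc[j] = std::max(0.0, sc + dprev);
          if (Mc[j] > best) best = Mc[j];
        } else {
          Mc[j] = (dprev == NEG_INF) ? NEG_INF : sc + dprev;
        }
        Xc[j] = max3(Mp[j] - gap_open, Xp[j] - gap_extend, Yp[j] - gap_open);
        Yc[j] = max3(Mc[j - 1] - gap_open, Xc[j - 1] - gap_open, Yc[j - 1] - gap_extend);
      }
      std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }
    out[p] = local ? best : max3(Mp[n], Xp[n], Yp[n]);
  }
  return out;
}
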