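#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense Prim MST with deterministic tie-breaking: among frontier vertices
// with equal key, the smallest index is added first; among equal-weight
// candidate edges into a vertex, the smallest parent index is kept.
// Returns (N-1) x 2 matrix of 1-based vertex pairs in insertion order.
static void prim_dense(const double* d, int N,
                       std::vector<int>& e1, std::vector<int>& e2,
                       std::vector<double>& key, std::vector<int>& parent,
                       std::vector<char>& intree) {
  for (int i = 0; i < N; ++i) {
    key[i] = d[i]; // column 0
    parent[i] = 0;
    intree[i] = 0;
  }
  intree[0] = 1;
  for (int t = 0; t < N - 1; ++t) {
    int v = -1;
    double best = R_PosInf;
    for (int i = 0; i < N; ++i) {
      if (!intree[i] && key[i] < best) { best = key[i]; v = i; }
    }
    e1[t] = parent[v];
    e2[t] = v;
    intree[v] = 1;
    const double* dv = d + (R_xlen_t)v * N;
    for (int i = 0; i < N; ++i) {
      if (intree[i]) continue;
      double w = dv[i];
      if (w < key[i] || (w == key[i] && v < parent[i])) {
        key[i] = w;
        parent[i] = v;
      }
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_mst(NumericMatrix d) {
  int N = d.nrow();
  if (N < 2) stop("need at least 2 points");
  std::vector<int> e1(N - 1), e2(N - 1), parent(N);
  std::vector<double> key(N);
  std::vector<char> intree(N);
  prim_dense(d.begin(), N, e1, e2, key, parent, intree);
  IntegerMatrix out(N - 1, 2);
  for (int t = 0; t < N - 1; ++t) {
    out(t, 0) = e1[t] + 1;
    out(t, 1) = e2[t] + 1;
  }
  return out;
}

// One (query cluster, reference cluster) pair of the iterative matching
// engine. Subsample indices are drawn in R (so the R RNG governs
// reproducibility) and passed as s x n_iter 1-based index matrices.
// For each iteration the pooled distance matrix is assembled from the
// precomputed within/cross blocks, the MST is built, and the one-sided
// normal p-value of the runs statistic is computed. Query cells drawn in
// an iteration have their running maximum p updated (max-update rule).
// Iterations with non-positive runs variance get p = NA and are reported
// in var_fail for an R-side permutation fallback.
// [[Rcpp::export]]
List cpp_match_pair(NumericMatrix Dqq, NumericMatrix Drr, NumericMatrix Dqr,
                    IntegerMatrix Qd, IntegerMatrix Rd) {
  const int s = Qd.nrow();
  const int T = Qd.ncol();
  const int N = 2 * s;
  const int nq = Dqq.nrow();
  if (Rd.nrow() != s || Rd.ncol() != T) stop("draw matrices must agree");
  if (N < 6) stop("pooled sample size must be at least 6");

  NumericVector p_iter(T);
  NumericVector best_p(nq, NA_REAL);
  IntegerVector coverage(nq);
  std::vector<int> fails;

  std::vector<double> pool((size_t)N * N);
  std::vector<int> e1(N - 1), e2(N - 1), parent(N), deg(N), qi(s), ri(s);
  std::vector<double> key(N);
  std::vector<char> intree(N);

  const double m = s, n = s, Nn = N;
  const double ER = 2.0 * m * n / Nn + 1.0;
  const double fac = 2.0 * m * n / (Nn * (Nn - 1.0));
  const double t1 = (2.0 * m * n - Nn) / Nn;
  const double t2 = Nn * (Nn - 1.0) - 4.0 * m * n + 2.0;

  for (int t = 0; t < T; ++t) {
    for (int a = 0; a < s; ++a) {
      qi[a] = Qd(a, t) - 1;
      ri[a] = Rd(a, t) - 1;
    }
    // pooled: query cells 0..s-1, reference cells s..N-1
    for (int j = 0; j < s; ++j) {
      double* colq = &pool[(size_t)j * N];
      double* colr = &pool[(size_t)(j + s) * N];
      for (int i = 0; i < s; ++i) {
        colq[i] = Dqq(qi[i], qi[j]);
        colq[i + s] = Dqr(qi[j], ri[i]); // symmetric use of cross block
        colr[i] = Dqr(qi[i], ri[j]);
        colr[i + s] = Drr(ri[i], ri[j]);
      }
    }
    prim_dense(pool.data(), N, e1, e2, key, parent, intree);
    int cross = 0;
    std::fill(deg.begin(), deg.end(), 0);
    for (int k = 0; k < N - 1; ++k) {
      ++deg[e1[k]];
      ++deg[e2[k]];
      if ((e1[k] < s) != (e2[k] < s)) ++cross;
    }
    double C = 0.0;
    for (int i = 0; i < N; ++i) C += deg[i] * (deg[i] - 1) / 2.0;
    const double R = cross + 1.0;
    const double VR =
        fac * (t1 + (C - Nn + 2.0) / ((Nn - 2.0) * (Nn - 3.0)) * t2);
    double p;
    if (VR <= 0.0) {
      p = NA_REAL;
      fails.push_back(t + 1);
    } else {
      p = R::pnorm((R - ER) / std::sqrt(VR), 0.0, 1.0, 1, 0);
    }
    p_iter[t] = p;
    for (int a = 0; a < s; ++a) {
      const int q = qi[a];
      ++coverage[q];
      if (!ISNA(p) && (NumericVector::is_na(best_p[q]) || p > best_p[q]))
        best_p[q] = p;
    }
  }
  return List::create(_["p_iter"] = p_iter, _["best_p"] = best_p,
                      _["coverage"] = coverage,
                      _["var_fail"] = wrap(fails));
}
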