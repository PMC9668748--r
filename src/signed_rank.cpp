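#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Paired Wilcoxon signed-rank engine used by the regional DE counting and the
// permutation / bootstrap resampling loops. One row of the input = one gene's
// per-subject paired differences (region_b - region_a).
//
// Tie policy (fixed so the permutation null reuses the identical rule):
//  * zero differences are dropped before ranking (classical Wilcoxon),
//  * |d| ties get midranks,
//  * n_nonzero <= exact_limit: exact two-sided p from the tie-aware null of
//    W+ (dynamic programming over doubled midranks, which are integers),
//  * otherwise: normal approximation with continuity correction; the midrank
//    variance sum(r_i^2)/4 carries the tie correction.
//
// The null of W+ is symmetric about sum(r)/2 even under ties (flipping all
// signs maps W+ to sum(r) - W+), so the two-sided p is 2 * P(W+ <= min(w,
// sum(r) - w)), capped at 1 — identical to enumerating all 2^n sign
// assignments and counting |W - mu| >= |w - mu|.

static double signed_rank_p_one(const std::vector<double>& d, int exact_limit,
                                std::vector<double>& absd,
                                std::vector<int>& ord,
                                std::vector<int>& rank2,
                                std::vector<double>& dp) {
  absd.clear();
  std::vector<double> vals;
  vals.reserve(d.size());
  for (double x : d) {
    if (!R_finite(x)) stop("non-finite paired difference");
    if (x != 0.0) vals.push_back(x);
  }
  const int n = (int)vals.size();
  if (n == 0) return 1.0;

  absd.resize(n);
  for (int i = 0; i < n; ++i) absd[i] = std::fabs(vals[i]);
  ord.resize(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return absd[a] < absd[b]; });

  // doubled midranks (integers even with ties)
  rank2.assign(n, 0);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && absd[ord[j + 1]] == absd[ord[i]]) ++j;
    // ranks i+1 .. j+1 averaged; doubled midrank = (i+1) + (j+1)
    int r2 = (i + 1) + (j + 1);
    for (int k = i; k <= j; ++k) rank2[ord[k]] = r2;
    i = j + 1;
  }

  long long W2 = 0;   // doubled W+
  long long R2 = 0;   // doubled sum of ranks = n(n+1)
  double sumsq = 0.0; // sum of squared (undoubled) midranks
  for (int k = 0; k < n; ++k) {
    R2 += rank2[k];
    double r = rank2[k] / 2.0;
    sumsq += r * r;
    if (vals[k] > 0) W2 += rank2[k];
  }

  if (n <= exact_limit) {
    // lower-tail mass of doubled W+ over 2^n sign assignments; the DP array
    // is truncated at m = min(W2, R2 - W2) <= R2/2 since only P(W+ <= m) is
    // needed (subset sums above m never re-enter the truncated range)
    const long long m = std::min(W2, R2 - W2);
    dp.assign((size_t)m + 1, 0.0);
    dp[0] = 1.0;
    for (int k = 0; k < n; ++k) {
      const int r = rank2[k];
      for (long long w = m; w >= r; --w) dp[(size_t)w] += dp[(size_t)(w - r)];
    }
    const double total = std::ldexp(1.0, n); // 2^n
    double tail = 0.0;
    for (long long w = 0; w <= m; ++w) tail += dp[(size_t)w];
    double p = 2.0 * tail / total;
    return p > 1.0 ? 1.0 : p;
  }

  // normal approximation with continuity correction
  const double Wp = W2 / 2.0;
  const double mu = R2 / 4.0;
  const double sd = std::sqrt(sumsq / 4.0);
  if (sd <= 0.0) return 1.0;
  double z = std::fabs(Wp - mu) - 0.5;
  if (z < 0.0) z = 0.0;
  double p = 2.0 * R::pnorm(-z / sd, 0.0, 1.0, 1, 0);
  return p > 1.0 ? 1.0 : p;
}

// [[Rcpp::export(name = ".cpp_signed_rank_p")]]
NumericVector cpp_signed_rank_p(NumericMatrix D, int exact_limit) {
  const int ng = D.nrow(), ns = D.ncol();
  NumericVector out(ng);
  std::vector<double> d(ns), absd, dp;
  std::vector<int> ord, rank2;
  for (int g = 0; g < ng; ++g) {
    for (int s = 0; s < ns; ++s) d[s] = D(g, s);
    out[g] = signed_rank_p_one(d, exact_limit, absd, ord, rank2, dp);
  }
  return out;
}

// Benjamini-Hochberg rejection count and the per-gene rejection flags at
// level alpha, without materializing q-values. Rejection is q < alpha
// (strict, matching count_de's de_flag), i.e. the largest i with
// p_(i) < alpha * i / m.
static int bh_rejected(const std::vector<double>& p, double alpha,
                       std::vector<char>* flags) {
  const int m = (int)p.size();
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return p[a] < p[b]; });
  int k = 0;
  for (int i = m; i >= 1; --i) {
    if (p[ord[i - 1]] < alpha * i / m) { k = i; break; }
  }
  if (flags) {
    flags->assign(m, 0);
    for (int i = 0; i < k; ++i) (*flags)[ord[i]] = 1;
  }
  return k;
}

// DE counts for each row of `idx` (1-based subject-column indices into D):
// per draw, run the signed-rank test on the selected columns for every gene,
// BH-adjust across genes, count q < alpha. Optionally accumulates, per gene,
// how many draws flagged it (the permutation-occurrence counter).
// [[Rcpp::export(name = ".cpp_de_counts")]]
List cpp_de_counts(NumericMatrix D, IntegerMatrix idx, double alpha,
                   int exact_limit, bool occurrence) {
  const int ng = D.nrow(), B = idx.nrow(), k = idx.ncol();
  IntegerVector counts(B);
  IntegerVector occ(occurrence ? ng : 0);
  std::vector<double> d(k), p(ng), absd, dp;
  std::vector<int> ord, rank2;
  std::vector<char> flags;
  for (int b = 0; b < B; ++b) {
    for (int g = 0; g < ng; ++g) {
      for (int s = 0; s < k; ++s) {
        int col = idx(b, s) - 1;
        d[s] = D(g, col);
      }
      p[g] = signed_rank_p_one(d, exact_limit, absd, ord, rank2, dp);
    }
    counts[b] = bh_rejected(p, alpha, occurrence ? &flags : (std::vector<char>*)nullptr);
    if (occurrence) {
      for (int g = 0; g < ng; ++g) occ[g] += flags[g];
    }
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  if (occurrence) return List::create(_["counts"] = counts, _["occurrence"] = occ);
  return List::create(_["counts"] = counts);
}
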