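#include <Rcpp.h>
using namespace Rcpp;

// Upper tail P(X >= n_obs) of a Poisson-binomial count X = sum of independent
// Bernoulli(p_a). Exact dynamic programming over the lower tail, truncated at
// n_obs - 1 states. Probabilities equal to 1 force the count and are handled
// outside the DP so the array stays small for sparse data.
static double pb_upper_tail(const double *p, int m, int n_obs) {
  if (n_obs <= 0) return 1.0;
  int forced = 0;
  std::vector<double> q;
  q.reserve(m);
  for (int a = 0; a < m; a++) {
    double pa = p[a];
    if (pa >= 1.0) forced++;
    else if (pa > 0.0) q.push_back(pa);
  }
  int target = n_obs - forced; // need X_free >= target
  if (target <= 0) return 1.0;
  int nfree = (int)q.size();
  if (target > nfree) return 0.0;
  // Truncated-count DP over whichever tail is shorter. The upper branch
  // accumulates P(failures <= nfree - target) = P(X >= target) directly,
  // avoiding the 1 - lower cancellation for deep tails.
  bool upper = (nfree - target) < (target - 1);
  int K = upper ? (nfree - target + 1) : target; // states 0 .. K-1
  std::vector<double> dp(K, 0.0);
  dp[0] = 1.0;
  int maxc = 0;
  for (int a = 0; a < nfree; a++) {
    double pa = upper ? (1.0 - q[a]) : q[a];
    int hi = std::min(maxc + 1, K - 1);
    for (int c = hi; c >= 1; c--) dp[c] = dp[c] * (1.0 - pa) + dp[c - 1] * pa;
    dp[0] *= (1.0 - pa);
    maxc = hi;
  }
  double acc = 0.0;
  for (int c = 0; c < K; c++) acc += dp[c];
  double tail = upper ? acc : 1.0 - acc;
  if (tail < 0.0) tail = 0.0;
  if (tail > 1.0) tail = 1.0;
  return tail;
}

// [[Rcpp::export(name = ".pb_tail_cpp")]]
double pb_tail_cpp(NumericVector probs, int n_obs) {
  return pb_upper_tail(probs.begin(), probs.size(), n_obs);
}

// Aggregation score for a single pair given presence rows and probability
// rows: S = -log P(X >= N) with N the observed co-occurrence count and
// per-sample success probability pi_i * pi_j.
static double pair_score(const int *xi, const int *xj,
                         const double *pi, const double *pj,
                         int m, int *n_out, double floor_eps) {
  int N = 0;
  std::vector<double> q(m);
  for (int a = 0; a < m; a++) {
    if (xi[a] == 1 && xj[a] == 1) N++;
    q[a] = pi[a] * pj[a];
  }
  *n_out = N;
  if (N == 0) return 0.0;
  double tail = pb_upper_tail(q.data(), m, N);
  if (tail < floor_eps) tail = floor_eps;
  return -std::log(tail);
}

// All unordered pairs of rows of X: observed co-occurrence count N and
// aggregation score S. X is an integer 0/1 matrix (rows = nodes), Pi the
// matching probability matrix.
// [[Rcpp::export(name = ".all_pair_scores_cpp")]]
List all_pair_scores_cpp(IntegerMatrix X, NumericMatrix Pi, double floor_eps) {
  int n = X.nrow(), m = X.ncol();
  R_xlen_t npair = (R_xlen_t)n * (n - 1) / 2;
  IntegerVector I(npair), J(npair), N(npair);
  NumericVector S(npair);
  std::vector<int> xi(m), xj(m);
  std::vector<double> pi(m), pj(m);
  R_xlen_t k = 0;
  for (int i = 0; i < n - 1; i++) {
    for (int a = 0; a < m; a++) { xi[a] = X(i, a); pi[a] = Pi(i, a); }
    for (int j = i + 1; j < n; j++) {
      for (int a = 0; a < m; a++) { xj[a] = X(j, a); pj[a] = Pi(j, a); }
      int nij;
      double s = pair_score(xi.data(), xj.data(), pi.data(), pj.data(),
                            m, &nij, floor_eps);
      I[k] = i + 1; J[k] = j + 1; N[k] = nij; S[k] = s;
      k++;
    }
  }
  return List::create(_["i"] = I, _["j"] = J, _["n_co"] = N, _["score"] = S);
}

// Scores for explicit index pairs (1-based rows of X / Pi).
// [[Rcpp::export(name = ".pair_scores_cpp")]]
List pair_scores_cpp(IntegerMatrix X, NumericMatrix Pi,
                     IntegerVector I, IntegerVector J, double floor_eps) {
  int m = X.ncol();
  R_xlen_t npair = I.size();
  IntegerVector N(npair);
  NumericVector S(npair);
  std::vector<int> xi(m), xj(m);
  std::vector<double> pi(m), pj(m);
  for (R_xlen_t k = 0; k < npair; k++) {
    int i = I[k] - 1, j = J[k] - 1;
    for (int a = 0; a < m; a++) {
      xi[a] = X(i, a); pi[a] = Pi(i, a);
      xj[a] = X(j, a); pj[a] = Pi(j, a);
    }
    int nij;
    S[k] = pair_score(xi.data(), xj.data(), pi.data(), pj.data(),
                      m, &nij, floor_eps);
    N[k] = nij;
  }
  return List::create(_["n_co"] = N, _["score"] = S);
}

// In-place curveball trades on a binary matrix. Each trade picks two distinct
// rows and randomly redistributes the columns held by exactly one of them,
// preserving all row and column totals. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export(name = ".curveball_cpp")]]
IntegerMatrix curveball_cpp(IntegerMatrix X, int n_trades) {
  IntegerMatrix M = clone(X);
  int n = M.nrow(), mcol = M.ncol();
  if (n < 2) return M;
  std::vector<int> diff_cols(mcol), own(mcol);
  for (int t = 0; t < n_trades; t++) {
    int r1 = (int)(R::unif_rand() * n);
    int r2 = (int)(R::unif_rand() * (n - 1));
    if (r2 >= r1) r2++;
    int ndiff = 0, n1 = 0;
    for (int a = 0; a < mcol; a++) {
      int v1 = M(r1, a), v2 = M(r2, a);
      if (v1 != v2) {
        diff_cols[ndiff++] = a;
        if (v1 == 1) n1++;
      }
    }
    if (ndiff < 2 || n1 == 0 || n1 == ndiff) continue;
    // choose n1 of the ndiff contested columns for r1 (partial Fisher-Yates)
    for (int a = 0; a < ndiff; a++) own[a] = 0;
    for (int pick = 0; pick < n1; pick++) {
      int idx = pick + (int)(R::unif_rand() * (ndiff - pick));
      std::swap(diff_cols[pick], diff_cols[idx]);
      own[pick] = 1;
    }
    for (int a = 0; a < ndiff; a++) {
      int col = diff_cols[a];
      M(r1, col) = own[a];
      M(r2, col) = 1 - own[a];
    }
  }
  return M;
}
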