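#include <Rcpp.h>
using namespace Rcpp;

// Tie-corrected Kendall tau-b by O(n^2) pair counting. Returns NA when a
// denominator term vanishes (a constant input).
static double tau_b(const double* x, const double* y, int n) {
  long long conc = 0, disc = 0, tx = 0, ty = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      if (dx == 0.0 && dy == 0.0) { ++tx; ++ty; }
      else if (dx == 0.0) ++tx;
      else if (dy == 0.0) ++ty;
      else if ((dx > 0.0) == (dy > 0.0)) ++conc;
      else ++disc;
    }
  }
  long long n0 = (long long)n * (n - 1) / 2;
  double d1 = (double)(n0 - tx), d2 = (double)(n0 - ty);
  if (d1 <= 0.0 || d2 <= 0.0) return NA_REAL;
  return (double)(conc - disc) / std::sqrt(d1 * d2);
}

// [[Rcpp::export]]
double kendall_tau_b(NumericVector x, NumericVector y) {
  if (x.size() != y.size()) stop("x and y must have equal length");
  return tau_b(x.begin(), y.begin(), x.size());
}

static void shuffle_in_place(std::vector<double>& v) {
  // Fisher-Yates driven by R's RNG so set.seed() governs reproducibility
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// Max Kendall tau over a bank of cosine templates, with a permutation
// null of the same max statistic (multiplicity of the template grid is
// absorbed into the null).
// [[Rcpp::export]]
List jtk_perm_kernel(NumericVector y, NumericMatrix templates, int nperm) {
  int n = y.size(), m = templates.ncol();
  if (templates.nrow() != n) stop("templates must have one row per observation");
  NumericVector obs(m);
  double obs_max = R_NegInf;
  bool any_defined = false;
  for (int k = 0; k < m; ++k) {
    obs[k] = tau_b(&templates(0, k), y.begin(), n);
    if (!NumericVector::is_na(obs[k])) {
      any_defined = true;
      if (obs[k] > obs_max) obs_max = obs[k];
    }
  }
  NumericVector null_max(nperm, NA_REAL);
  if (any_defined && nperm > 0) {
    std::vector<double> perm(y.begin(), y.end());
    for (int p = 0; p < nperm; ++p) {
      shuffle_in_place(perm);
      double best = R_NegInf;
      for (int k = 0; k < m; ++k) {
        double t = tau_b(&templates(0, k), perm.data(), n);
        if (!ISNA(t) && t > best) best = t;
      }
      null_max[p] = best;
    }
  }
  return List::create(_["obs_tau"] = obs,
                      _["obs_max"] = any_defined ? obs_max : NA_REAL,
                      _["null_max"] = null_max);
}

// Mack-Wolfe umbrella statistics for all candidate peak groups, from the
// matrix of pairwise Mann-Whitney counts U[i][j] = #{x in group i < y in
// group j} (+ 1/2 per tie). Group labels are 0..K-1 in folded-time order.
static void umbrella_stats(const double* y, const int* g, int n, int K,
                           const std::vector<double>& mean_k,
                           const std::vector<double>& sd_k,
                           std::vector<double>& stat_out) {
  std::vector<double> U(K * K, 0.0);
  for (int a = 0; a < n - 1; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int gi = g[a], gj = g[b];
      if (gi == gj) continue;
      double xa = y[a], xb = y[b];
      if (xa == xb) { U[gi * K + gj] += 0.5; U[gj * K + gi] += 0.5; }
      else if (xa < xb) U[gi * K + gj] += 1.0;   // group of a below group of b
      else U[gj * K + gi] += 1.0;
    }
  }
  // prefix sums: rising arm counts up to peak, falling arm beyond it
  for (int p = 0; p < K; ++p) {
    double A = 0.0;
    for (int i = 0; i <= p; ++i)
      for (int j = i + 1; j <= p; ++j) A += U[i * K + j];
    for (int i = p; i < K; ++i)
      for (int j = i + 1; j < K; ++j) A += U[j * K + i];
    stat_out[p] = (sd_k[p] > 0.0) ? (A - mean_k[p]) / sd_k[p] : 0.0;
  }
}

// [[Rcpp::export]]
List umbrella_perm_kernel(NumericVector y, IntegerVector group, int K,
                          int nperm) {
  int n = y.size();
  if (group.size() != n) stop("group must have one entry per observation");
  std::vector<double> nsz(K, 0.0);
  for (int i = 0; i < n; ++i) {
    if (group[i] < 0 || group[i] >= K) stop("group label outside 0..K-1");
    nsz[group[i]] += 1.0;
  }
  double N = n, sum_n2 = 0.0, sum_n2_2n3 = 0.0;
  for (int i = 0; i < K; ++i) {
    sum_n2 += nsz[i] * nsz[i];
    sum_n2_2n3 += nsz[i] * nsz[i] * (2.0 * nsz[i] + 3.0);
  }
  // Mack-Wolfe null mean and variance (no-tie formulas; the permutation
  // null makes the test exact regardless of ties)
  std::vector<double> mean_k(K), sd_k(K);
  for (int p = 0; p < K; ++p) {
    double N1 = 0.0, N2 = 0.0;
    for (int i = 0; i <= p; ++i) N1 += nsz[i];
    for (int i = p; i < K; ++i) N2 += nsz[i];
    double np = nsz[p];
    mean_k[p] = (N1 * N1 + N2 * N2 - sum_n2 - np * np) / 4.0;
    double var = (2.0 * (N1 * N1 * N1 + N2 * N2 * N2)
                  + 3.0 * (N1 * N1 + N2 * N2)
                  - sum_n2_2n3 - np * np * (2.0 * np + 3.0)
                  + 12.0 * np * N1 * N2 - 12.0 * np * np * N) / 72.0;
    sd_k[p] = var > 0.0 ? std::sqrt(var) : 0.0;
  }
  std::vector<double> stat(K);
  umbrella_stats(y.begin(), group.begin(), n, K, mean_k, sd_k, stat);
  NumericVector obs(stat.begin(), stat.end());
  NumericVector null_max(nperm);
  std::vector<double> perm(y.begin(), y.end());
  std::vector<double> pstat(K);
  for (int p = 0; p < nperm; ++p) {
    shuffle_in_place(perm);
    umbrella_stats(perm.data(), group.begin(), n, K, mean_k, sd_k, pstat);
    null_max[p] = *std::max_element(pstat.begin(), pstat.end());
  }
  return List::create(_["obs_stat"] = obs, _["null_max"] = null_max);
}
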