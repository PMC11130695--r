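#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Weighted Jonckheere-Terpstra pairwise-concordance statistic:
//   U = sum over observation pairs (a, b) with group(a) < group(b) of
//       w_a * w_b * k(x_a, x_b),  k = 1 if x_a < x_b, 0.5 if x_a == x_b.
// One pass over tie blocks in ascending x keeps an evaluation O(n * k)
// after a single sort, which is what makes Monte-Carlo permutation
// nulls affordable. The tie-block structure depends on x only, so it
// is precomputed once and reused across label permutations.

static std::vector<int> sort_order(const double *x, int n) {
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return x[a] < x[b]; });
  return ord;
}

// block starts in sorted order; blk has size B + 1 with blk.back() == n
static std::vector<int> tie_blocks(const double *x,
                                   const std::vector<int> &ord) {
  const int n = ord.size();
  std::vector<int> blk;
  blk.push_back(0);
  for (int i = 1; i < n; ++i) {
    if (x[ord[i]] != x[ord[i - 1]]) blk.push_back(i);
  }
  blk.push_back(n);
  return blk;
}

static double jt_u_eval(const std::vector<int> &ord,
                        const std::vector<int> &blk, const int *g,
                        const double *w, int k, double *cumw,
                        double *blockw) {
  std::memset(cumw, 0, k * sizeof(double));
  double U = 0.0;
  for (size_t b = 0; b + 1 < blk.size(); ++b) {
    std::memset(blockw, 0, k * sizeof(double));
    for (int p = blk[b]; p < blk[b + 1]; ++p) {
      const int o = ord[p];
      blockw[g[o] - 1] += w[o];
    }
    double pref = 0.0, bpref = 0.0;
    for (int gg = 0; gg < k; ++gg) {
      // strictly smaller x in a lower group (kernel 1) plus
      // within-block ties across ordered group pairs (kernel 0.5)
      U += blockw[gg] * (pref + 0.5 * bpref);
      pref += cumw[gg];
      bpref += blockw[gg];
      cumw[gg] += blockw[gg];
    }
  }
  return U;
}

// [[Rcpp::export]]
double jt_u_cpp(NumericVector x, IntegerVector g, NumericVector w, int k) {
  const int n = x.size();
  std::vector<int> ord = sort_order(REAL(x), n);
  std::vector<int> blk = tie_blocks(REAL(x), ord);
  std::vector<double> cumw(k), blockw(k);
  return jt_u_eval(ord, blk, INTEGER(g), REAL(w), k, cumw.data(),
                   blockw.data());
}

// Observed U plus n_perm draws from the permutation null obtained by
// shuffling (group label, weight) pairs over observation slots, within
// strata when `strata` has more than one level (conditional null:
// outcome independent of group given stratum). With a single stratum
// and unit weights this is the classical unrestricted label
// permutation. Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List jt_perm_cpp(NumericVector x, IntegerVector g, NumericVector w, int k,
                 int n_perm, IntegerVector strata) {
  const int n = x.size();
  std::vector<int> ord = sort_order(REAL(x), n);
  std::vector<int> blk = tie_blocks(REAL(x), ord);
  std::vector<double> cumw(k), blockw(k);
  const double u_obs = jt_u_eval(ord, blk, INTEGER(g), REAL(w), k,
                                 cumw.data(), blockw.data());

  // observation slots per stratum
  int n_str = 0;
  for (int i = 0; i < n; ++i) n_str = std::max(n_str, strata[i]);
  std::vector<std::vector<int>> slots(n_str);
  for (int i = 0; i < n; ++i) slots[strata[i] - 1].push_back(i);

  std::vector<int> gp(INTEGER(g), INTEGER(g) + n);
  std::vector<double> wp(REAL(w), REAL(w) + n);
  NumericVector u_perm(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    for (const auto &idx : slots) {
      const int m = idx.size();
      for (int i = m - 1; i > 0; --i) {  // Fisher-Yates within stratum
        int j = static_cast<int>(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(gp[idx[i]], gp[idx[j]]);
        std::swap(wp[idx[i]], wp[idx[j]]);
      }
    }
    u_perm[p] = jt_u_eval(ord, blk, gp.data(), wp.data(), k, cumw.data(),
                          blockw.data());
  }
  return List::create(_["u"] = u_obs, _["u_perm"] = u_perm);
}
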