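#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Elimination (rank-sum) training count for one 0-based permutation:
// states trained in ascending order; cost of a state = 1 + number of
// not-yet-learned intentions probed (ascending) before the correct one;
// learned intentions leave the candidate pool.
static int ranksum_count0(const std::vector<int>& perm) {
  const int n = static_cast<int>(perm.size());
  std::vector<char> learned(n, 0);
  int total = 0;
  for (int s = 0; s < n; ++s) {
    int pos = 0;
    for (int j = 0; j < n; ++j) {
      if (learned[j]) continue;
      ++pos;
      if (j == perm[s]) break;
    }
    total += pos;
    learned[perm[s]] = 1;
  }
  return total;
}

// Tabular Q-learning baseline, reconstructed: per-state independent Q row,
// zero init, greedy lowest-index argmax, rewards +1/-1, learning rate 1.
static int qlearn_count0(const std::vector<int>& perm) {
  const int n = static_cast<int>(perm.size());
  int total = 0;
  std::vector<double> q(n);
  for (int s = 0; s < n; ++s) {
    std::fill(q.begin(), q.end(), 0.0);
    for (;;) {
      int a = 0;
      for (int j = 1; j < n; ++j) if (q[j] > q[a]) a = j;
      ++total;
      if (a == perm[s]) { q[a] += 1.0; break; }
      q[a] -= 1.0;
    }
  }
  return total;
}

static int count_one(const std::vector<int>& perm, const std::string& model) {
  if (model == "ranksum") return ranksum_count0(perm);
  if (model == "qlearn") return qlearn_count0(perm);
  stop("unknown model '%s'", model.c_str());
  return NA_INTEGER; // not reached
}

// [[Rcpp::export]]
IntegerVector rule_count_all_cpp(int n, std::string model) {
  if (n < 1 || n > 10) stop("exhaustive enumeration supports 1 <= n <= 10");
  double n_rules = 1.0;
  for (int k = 2; k <= n; ++k) n_rules *= k;
  IntegerVector out(static_cast<R_xlen_t>(n_rules));
  std::vector<int> perm(n);
  for (int j = 0; j < n; ++j) perm[j] = j;
  R_xlen_t idx = 0;
  do {
    out[idx++] = count_one(perm, model);
  } while (std::next_permutation(perm.begin(), perm.end()));
  return out;
}

// [[Rcpp::export]]
IntegerVector rule_count_perms_cpp(IntegerMatrix perms, std::string model) {
  const int n = perms.nrow();
  const R_xlen_t m = perms.ncol();
  IntegerVector out(m);
  std::vector<int> perm(n);
  for (R_xlen_t k = 0; k < m; ++k) {
    for (int j = 0; j < n; ++j) perm[j] = perms(j, k) - 1; // 1-based in R
    out[k] = count_one(perm, model);
  }
  return out;
}
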