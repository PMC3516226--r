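#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// longest gap-bounded strictly monotone chain over anchors (ra, rb):
// consecutive chain members differ by 1..max_gap ranks on both sides and
// rank_b follows a single direction. Anchors are sorted by rank_a here.
static int chain_len_dir(const std::vector<int>& ra,
                         const std::vector<int>& rb,
                         int max_gap, int dir) {
  int n = ra.size();
  std::vector<int> f(n, 1);
  int best = n > 0 ? 1 : 0;
  for (int j = 1; j < n; ++j) {
    for (int i = j - 1; i >= 0; --i) {
      int da = ra[j] - ra[i];
      if (da > max_gap) break; // sorted by ra: earlier i only further away
      if (da < 1) continue;
      int db = dir * (rb[j] - rb[i]);
      if (db >= 1 && db <= max_gap && f[i] + 1 > f[j]) f[j] = f[i] + 1;
    }
    if (f[j] > best) best = f[j];
  }
  return best;
}

static int max_chain_int(std::vector<int> ra, std::vector<int> rb,
                         int max_gap) {
  int n = ra.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (ra[a] != ra[b]) return ra[a] < ra[b];
    return rb[a] < rb[b];
  });
  std::vector<int> sa(n), sb(n);
  for (int i = 0; i < n; ++i) { sa[i] = ra[idx[i]]; sb[i] = rb[idx[i]]; }
  int up = chain_len_dir(sa, sb, max_gap, 1);
  int dn = chain_len_dir(sa, sb, max_gap, -1);
  return up > dn ? up : dn;
}

// [[Rcpp::export(name = ".max_chain_cpp")]]
int max_chain_cpp(IntegerVector ra, IntegerVector rb, int max_gap) {
  return max_chain_int(as<std::vector<int>>(ra),
                       as<std::vector<int>>(rb), max_gap);
}

// null distribution of the max gap-bounded chain when gene ranks are
// permuted within both chromosomes: A anchors land on uniformly random
// distinct ranks of each chromosome, with random association.
// Uses R's RNG so results reproduce under set.seed.
// [[Rcpp::export(name = ".chain_null_cpp")]]
IntegerVector chain_null_cpp(int n_genes_a, int n_genes_b, int n_anchors,
                             int max_gap, int n_shuffles) {
  RNGScope scope;
  int A = n_anchors;
  std::vector<int> pool_a(n_genes_a), pool_b(n_genes_b);
  IntegerVector out(n_shuffles);
  std::vector<int> ra(A), rb(A);
  for (int s = 0; s < n_shuffles; ++s) {
    for (int i = 0; i < n_genes_a; ++i) pool_a[i] = i;
    for (int i = 0; i < n_genes_b; ++i) pool_b[i] = i;
    for (int i = 0; i < A; ++i) { // partial Fisher-Yates draws
      int j = i + (int)(unif_rand() * (n_genes_a - i));
      if (j >= n_genes_a) j = n_genes_a - 1;
      std::swap(pool_a[i], pool_a[j]);
      int k = i + (int)(unif_rand() * (n_genes_b - i));
      if (k >= n_genes_b) k = n_genes_b - 1;
      std::swap(pool_b[i], pool_b[k]);
      ra[i] = pool_a[i];
      rb[i] = pool_b[i];
    }
    out[s] = max_chain_int(ra, rb, max_gap);
  }
  return out;
}
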