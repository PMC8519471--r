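#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Encoding: 0=A, 1=C, 2=G, 3=T(U). Watson-Crick + GU wobble.
static inline bool can_pair(int a, int b) {
  int x = a < b ? a : b;
  int y = a < b ? b : a;
  return (x == 0 && y == 3) || (x == 1 && y == 2) || (x == 2 && y == 3);
}

// Partition function over all nested secondary structures of `seq` with a
// uniform Boltzmann weight `w = exp(-E_pair/RT)` per base pair and a minimum
// hairpin loop of `minloop` unpaired nt. Positions in [block_from, block_to)
// (0-based) are forbidden from pairing, which yields the constrained
// partition function Z_unpaired for that interval; pass block_from >=
// block_to for the unconstrained total Z.
// [[Rcpp::export]]
double toy_partition_cpp(IntegerVector seq, double w, int minloop,
                         int block_from, int block_to) {
  int n = seq.size();
  if (n == 0) return 1.0;
  std::vector<double> Z((size_t)n * n, 1.0);
  auto at = [n](std::vector<double>& M, int i, int j) -> double& {
    return M[(size_t)i * n + j];
  };
  auto blocked = [&](int k) { return k >= block_from && k < block_to; };
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double z = at(Z, i, j - 1); // j unpaired
      if (!blocked(j)) {
        for (int k = i; k <= j - minloop - 1; ++k) {
          if (blocked(k) || !can_pair(seq[k], seq[j])) continue;
          double left = (k > i) ? at(Z, i, k - 1) : 1.0;
          double inner = (j - k >= 2) ? at(Z, k + 1, j - 1) : 1.0;
          z += left * w * inner;
        }
      }
      at(Z, i, j) = z;
    }
  }
  return at(Z, 0, n - 1);
}

// Maximum number of base pairs over nested structures (Nussinov) with the
// same pairing rules; toy minimum free energy = pair_energy * max pairs.
// [[Rcpp::export]]
int toy_max_pairs_cpp(IntegerVector seq, int minloop) {
  int n = seq.size();
  if (n == 0) return 0;
  std::vector<int> N((size_t)n * n, 0);
  auto at = [n](std::vector<int>& M, int i, int j) -> int& {
    return M[(size_t)i * n + j];
  };
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = at(N, i, j - 1);
      for (int k = i; k <= j - minloop - 1; ++k) {
        if (!can_pair(seq[k], seq[j])) continue;
        int left = (k > i) ? at(N, i, k - 1) : 0;
        int inner = (j - k >= 2) ? at(N, k + 1, j - 1) : 0;
        int cand = left + 1 + inner;
        if (cand > best) best = cand;
      }
      at(N, i, j) = best;
    }
  }
  return at(N, 0, n - 1);
}
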