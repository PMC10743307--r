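#include <Rcpp.h>
using namespace Rcpp;

// Kernels operating on delay-embedded series. The embedding is passed
// transposed (m x n, one lagged vector per column) so distance evaluations
// touch contiguous memory.

static inline double edist(const double* E, int m, int a, int b) {
  const double* pa = E + (size_t) m * a;
  const double* pb = E + (size_t) m * b;
  double s = 0.0;
  for (int j = 0; j < m; ++j) { const double d = pa[j] - pb[j]; s += d * d; }
  return std::sqrt(s);
}

// Sample of admissible pair distances (used to pick r* and shell ranges).
// idx: 0-based column indices of the vectors entering the pair search.
// [[Rcpp::export]]
NumericVector cpp_pair_dist_sample(NumericMatrix emb, IntegerVector idx,
                                   int theiler) {
  const int m = emb.nrow();
  const double* E = REAL(emb);
  std::vector<double> out;
  out.reserve((size_t) idx.size() * (idx.size() - 1) / 2);
  for (int a = 0; a < idx.size(); ++a) {
    for (int b = a + 1; b < idx.size(); ++b) {
      if (std::abs(idx[b] - idx[a]) <= theiler) continue;
      out.push_back(edist(E, m, idx[a], idx[b]));
    }
  }
  return wrap(out);
}

// Gao-Zheng pair-separation curve: Lambda(k) = < ln(d_k / d_0) > over pairs
// with d_0 < r_star and temporal separation > theiler. Pair origins must
// leave room for k_max evolution steps (enforced by the caller through idx).
// [[Rcpp::export]]
List cpp_gz(NumericMatrix emb, IntegerVector idx, double r_star, int k_max,
            int theiler, int max_pairs) {
  const int m = emb.nrow();
  const double* E = REAL(emb);
  std::vector<int> pa, pb;
  for (int a = 0; a < idx.size() && (int) pa.size() < max_pairs; ++a) {
    for (int b = a + 1; b < idx.size() && (int) pa.size() < max_pairs; ++b) {
      if (std::abs(idx[b] - idx[a]) <= theiler) continue;
      const double d0 = edist(E, m, idx[a], idx[b]);
      if (d0 > 0.0 && d0 < r_star) { pa.push_back(idx[a]); pb.push_back(idx[b]); }
    }
  }
  const int np = (int) pa.size();
  NumericVector Lambda(k_max + 1);
  if (np == 0) return List::create(_["Lambda"] = Lambda, _["n_pairs"] = 0);
  for (int k = 0; k <= k_max; ++k) {
    double acc = 0.0; int cnt = 0;
    for (int p = 0; p < np; ++p) {
      const double d0 = edist(E, m, pa[p], pb[p]);
      const double dk = edist(E, m, pa[p] + k, pb[p] + k);
      if (d0 > 0.0 && dk > 0.0) { acc += std::log(dk / d0); ++cnt; }
    }
    Lambda[k] = cnt > 0 ? acc / cnt : NA_REAL;
  }
  return List::create(_["Lambda"] = Lambda, _["n_pairs"] = np);
}

// Scale-dependent Lyapunov exponent: pairs are grouped by the shell holding
// their INITIAL separation; each pair then contributes its log-separation
// growth increments over evolution times t (in steps of dt) to that shell,
// until the separation saturates at the attractor size (`sat`) or the
// horizon is reached.
// bounds: strictly increasing shell boundaries, length K+1.
// [[Rcpp::export]]
List cpp_sdle(NumericMatrix emb, IntegerVector idx, NumericVector bounds,
              int theiler, int dt, int horizon, double sat, int max_pairs) {
  const int m = emb.nrow();
  const double* E = REAL(emb);
  const int K = bounds.size() - 1;
  std::vector<double> sums(K, 0.0), sums2(K, 0.0);
  std::vector<int> cnts(K, 0), npairs(K, 0);
  int used = 0;
  for (int a = 0; a < idx.size() && used < max_pairs; ++a) {
    for (int b = a + 1; b < idx.size() && used < max_pairs; ++b) {
      if (std::abs(idx[b] - idx[a]) <= theiler) continue;
      ++used;
      const double d0 = edist(E, m, idx[a], idx[b]);
      if (d0 <= 0.0 || d0 < bounds[0] || d0 >= bounds[K] || d0 > sat)
        continue;
      int lo = 0, hi = K;
      while (hi - lo > 1) { const int mid = (lo + hi) / 2;
        if (d0 >= bounds[mid]) lo = mid; else hi = mid; }
      bool any = false;
      for (int t = 0; t <= horizon; ++t) {
        const double da = edist(E, m, idx[a] + t, idx[b] + t);
        if (da <= 0.0) continue;
        if (da > sat) break;
        const double db = edist(E, m, idx[a] + t + dt, idx[b] + t + dt);
        if (db <= 0.0) continue;
        const double inc = std::log(db / da);
        sums[lo] += inc;
        sums2[lo] += inc * inc;
        cnts[lo] += 1;
        any = true;
      }
      if (any) npairs[lo] += 1;
    }
  }
  return List::create(_["sums"] = wrap(sums), _["sums2"] = wrap(sums2),
                      _["counts"] = wrap(cnts),
                      _["n_pairs"] = wrap(npairs), _["pairs_used"] = used);
}
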