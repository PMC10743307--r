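#include <Rcpp.h>
using namespace Rcpp;

// Pair-histogram engine behind the connected correlation functions.
//
// pos, dvhat: T x N x 2 arrays (R dim vectors). Positions are reduced to the
// center-of-mass frame per frame before distances are taken. For every lag t
// and time origin t0, all ordered pairs (i, j) -- including i = j -- contribute
// weight dvhat_i(t0) . dvhat_j(t0 + t) to the bin holding
// r_ij = | r_i(t0) - r_j(t0 + t) |. Bins are uniform on [0, rmax].
// [[Rcpp::export]]
List cpp_corr_hist(NumericVector pos, NumericVector dvhat,
                   IntegerVector t0_idx, IntegerVector lags,
                   int nbins, double rmax) {
  IntegerVector dims = pos.attr("dim");
  const int T = dims[0], N = dims[1];
  const double* P = REAL(pos);
  const double* V = REAL(dvhat);
  // center-of-mass per frame
  std::vector<double> cmx(T, 0.0), cmy(T, 0.0);
  for (int t = 0; t < T; ++t) {
    double sx = 0.0, sy = 0.0;
    for (int i = 0; i < N; ++i) {
      sx += P[t + (size_t) T * i];
      sy += P[t + (size_t) T * (i + N)];
    }
    cmx[t] = sx / N; cmy[t] = sy / N;
  }
  const int nl = lags.size();
  NumericMatrix W(nl, nbins);
  NumericMatrix CNT(nl, nbins);
  IntegerVector n_origins(nl);
  std::vector<double> ax(N), ay(N), bx(N), by(N), ux(N), uy(N), wx(N), wy(N);
  const double binf = nbins / rmax;
  for (int l = 0; l < nl; ++l) {
    const int lag = lags[l];
    for (int k = 0; k < t0_idx.size(); ++k) {
      const int t0 = t0_idx[k];
      const int t1 = t0 + lag;
      if (t1 >= T) continue;
      n_origins[l] += 1;
      for (int i = 0; i < N; ++i) {
        ax[i] = P[t0 + (size_t) T * i] - cmx[t0];
        ay[i] = P[t0 + (size_t) T * (i + N)] - cmy[t0];
        bx[i] = P[t1 + (size_t) T * i] - cmx[t1];
        by[i] = P[t1 + (size_t) T * (i + N)] - cmy[t1];
        ux[i] = V[t0 + (size_t) T * i];
        uy[i] = V[t0 + (size_t) T * (i + N)];
        wx[i] = V[t1 + (size_t) T * i];
        wy[i] = V[t1 + (size_t) T * (i + N)];
      }
      for (int i = 0; i < N; ++i) {
        const double axi = ax[i], ayi = ay[i], uxi = ux[i], uyi = uy[i];
        for (int j = 0; j < N; ++j) {
          const double dx = axi - bx[j], dy = ayi - by[j];
          const double r = std::sqrt(dx * dx + dy * dy);
          int b = (int) (r * binf);
          if (b >= nbins) b = nbins - 1;
          W(l, b) += uxi * wx[j] + uyi * wy[j];
          CNT(l, b) += 1.0;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["W"] = W, _["CNT"] = CNT, _["n_origins"] = n_origins);
}

// Maximum interparticle distance per frame (swarm size).
// [[Rcpp::export]]
NumericVector cpp_max_pairdist(NumericVector pos, IntegerVector frames) {
  IntegerVector dims = pos.attr("dim");
  const int T = dims[0], N = dims[1];
  const double* P = REAL(pos);
  NumericVector out(frames.size());
  for (int k = 0; k < frames.size(); ++k) {
    const int t = frames[k];
    double best = 0.0;
    for (int i = 0; i < N; ++i) {
      const double xi = P[t + (size_t) T * i], yi = P[t + (size_t) T * (i + N)];
      for (int j = i + 1; j < N; ++j) {
        const double dx = xi - P[t + (size_t) T * j];
        const double dy = yi - P[t + (size_t) T * (j + N)];
        const double d2 = dx * dx + dy * dy;
        if (d2 > best) best = d2;
      }
    }
    out[k] = std::sqrt(best);
  }
  return out;
}

// Generalized correlation integrals for the multifractal spectrum.
// For each radius r in r_grid (ascending) computes the per-point neighbor
// fractions p_i(r) = (#{j: |x_i - x_j| <= r}) / M with the self pair included,
// then returns mean_i p_i^(q-1) for each q != 1 and mean_i ln p_i (the q -> 1
// information-dimension limit).
// [[Rcpp::export]]
List cpp_corr_integral(NumericVector x, NumericVector y,
                       NumericVector r_grid, NumericVector q_grid) {
  const int M = x.size();
  const int nr = r_grid.size();
  const int nq = q_grid.size();
  std::vector<int> hist((size_t) M * nr, 0);
  const double rmax = r_grid[nr - 1];
  for (int i = 0; i < M; ++i) {
    const double xi = x[i], yi = y[i];
    for (int j = i + 1; j < M; ++j) {
      const double dx = xi - x[j], dy = yi - y[j];
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d > rmax) continue;
      // first grid index with r_grid[k] >= d
      int lo = 0, hi = nr - 1;
      if (d > r_grid[0]) {
        while (hi - lo > 1) { const int mid = (lo + hi) / 2;
          if (d > r_grid[mid]) lo = mid; else hi = mid; }
        lo = hi;
      }
      hist[(size_t) i * nr + lo] += 1;
      hist[(size_t) j * nr + lo] += 1;
    }
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix Cq(nr, nq);
  NumericVector lnp(nr);
  std::vector<double> cum(M, 1.0);  // self pair
  for (int k = 0; k < nr; ++k) {
    for (int i = 0; i < M; ++i) cum[i] += hist[(size_t) i * nr + k];
    double sl = 0.0;
    for (int i = 0; i < M; ++i) sl += std::log(cum[i] / M);
    lnp[k] = sl / M;
    for (int qi = 0; qi < nq; ++qi) {
      const double q = q_grid[qi];
      if (q == 1.0) { Cq(k, qi) = NA_REAL; continue; }
      double s = 0.0;
      for (int i = 0; i < M; ++i) s += std::pow(cum[i] / M, q - 1.0);
      Cq(k, qi) = s / M;
    }
  }
  return List::create(_["Cq"] = Cq, _["mean_log_p"] = lnp);
}
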