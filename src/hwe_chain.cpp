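#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Guo-Thompson style switching chain over diploid genotype count tables,
// conditioned on the allele counts (Levene's distribution).
//
// State: symmetric k x k genotype count matrix (n[i][j] individuals with
// unordered genotype {i,j}).  Move: pick two distinct individuals, pick one
// allele from each, swap them.  Metropolis-Hastings acceptance uses the
// stationary probability  pi(T) propto 2^H / prod n_ij!  together with the
// forward/reverse pathway proposal probabilities.
//
// Returned are per-batch means of three indicators -- Pr(table) <= Pr(obs)
// (probability test), H <= H_obs (heterozygote deficit) and H >= H_obs
// (excess) -- plus, optionally, the per-iteration heterozygote count trace
// used for multilocus joint resampling.  R's RNG is used so runs are
// reproducible from set.seed().

static inline int cidx(int i, int j, int k) {
  // index into dense k*k matrix, canonical i <= j
  if (i > j) { int t = i; i = j; j = t; }
  return i * k + j;
}

// [[Rcpp::export(name = ".gt_chain_cpp")]]
List gt_chain_cpp(IntegerMatrix counts, int demem, int batches,
                  int iter_per_batch, bool keep_trace) {
  int k = counts.nrow();
  std::vector<double> m(k * k, 0.0);
  int n = 0, H = 0;
  double logw = 0.0;  // H*log2 - sum lgamma(m_ij + 1)
  for (int i = 0; i < k; ++i)
    for (int j = i; j < k; ++j) {
      double c = counts(i, j) + (i == j ? 0 : counts(j, i));
      m[cidx(i, j, k)] = c;
      n += (int)c;
      if (i != j) H += (int)c;
      logw -= lgamma(c + 1.0);
    }
  logw += H * M_LN2;
  const double logw_obs = logw;
  const int H_obs = H;
  const double tol = 1e-9;

  if (n < 2) {
    NumericVector one(batches, 1.0);
    return List::create(_["prob"] = one, _["deficit"] = one,
                        _["excess"] = one,
                        _["H_trace"] = IntegerVector(0),
                        _["accept_rate"] = 0.0);
  }

  // flat list of genotype cells with counts for individual sampling
  RNGScope scope;
  NumericVector prob(batches), def(batches), exc(batches);
  IntegerVector trace(keep_trace ? batches * iter_per_batch : 0);
  long accepted = 0, proposed = 0;
  long total = demem + (long)batches * iter_per_batch;

  for (long step = 0; step < total; ++step) {
    // pick two distinct individuals by cell, weighted by counts
    double u1 = unif_rand() * n;
    int g1i = -1, g1j = -1;
    double acc = 0.0;
    for (int i = 0; i < k && g1i < 0; ++i)
      for (int j = i; j < k; ++j) {
        acc += m[cidx(i, j, k)];
        if (u1 < acc) { g1i = i; g1j = j; break; }
      }
    // second individual from remaining n-1
    double u2 = unif_rand() * (n - 1);
    int g2i = -1, g2j = -1;
    acc = 0.0;
    for (int i = 0; i < k && g2i < 0; ++i)
      for (int j = i; j < k; ++j) {
        double c = m[cidx(i, j, k)];
        if (i == g1i && j == g1j) c -= 1.0;
        acc += c;
        if (u2 < acc) { g2i = i; g2j = j; break; }
      }
    // pick one allele from each
    int x = (g1i == g1j) ? g1i : (unif_rand() < 0.5 ? g1i : g1j);
    int keep1 = (x == g1i) ? g1j : g1i;
    int y = (g2i == g2j) ? g2i : (unif_rand() < 0.5 ? g2i : g2j);
    int keep2 = (y == g2i) ? g2j : g2i;

    bool same_cell = (g1i == g2i && g1j == g2j);
    double stat_here;  // record after the move below
    if (x == y) {
      // no-op proposal, always "accepted" (state unchanged)
      stat_here = 0;
      proposed++;
    } else {
      proposed++;
      // forward selection factor and allele-pick probabilities
      double n_g1 = m[cidx(g1i, g1j, k)];
      double n_g2 = m[cidx(g2i, g2j, k)] - (same_cell ? 1.0 : 0.0);
      double p_fwd = (g1i == g1j ? 1.0 : 0.5) * (g2i == g2j ? 1.0 : 0.5);
      double C_fwd = n_g1 * n_g2;

      // new genotypes
      int h1i = std::min(keep1, y), h1j = std::max(keep1, y);
      int h2i = std::min(keep2, x), h2j = std::max(keep2, x);

      // apply move on a scratch basis, accumulating log-factorial delta
      double dlogfact = 0.0;
      int c1 = cidx(g1i, g1j, k), c2 = cidx(g2i, g2j, k);
      int d1 = cidx(h1i, h1j, k), d2 = cidx(h2i, h2j, k);
      // decrement g1, g2; increment h1, h2 (sequentially, handles overlaps)
      dlogfact -= std::log(m[c1]); m[c1] -= 1.0;
      dlogfact -= std::log(m[c2]); m[c2] -= 1.0;
      m[d1] += 1.0; dlogfact += std::log(m[d1]);
      m[d2] += 1.0; dlogfact += std::log(m[d2]);

      int dH = (g1i == g1j ? 0 : -1) + (g2i == g2j ? 0 : -1) +
               (h1i == h1j ? 0 : 1) + (h2i == h2j ? 0 : 1);
      double dlogpi = dH * M_LN2 - dlogfact;

      bool samenew = (d1 == d2);
      double n_h1 = m[d1];
      double n_h2 = m[d2] - (samenew ? 1.0 : 0.0);
      double p_rev = (h1i == h1j ? 1.0 : 0.5) * (h2i == h2j ? 1.0 : 0.5);
      double C_rev = n_h1 * n_h2;

      double logA = dlogpi + std::log(C_rev * p_rev) -
                    std::log(C_fwd * p_fwd);
      if (logA >= 0.0 || std::log(unif_rand()) < logA) {
        H += dH;
        logw += dlogpi;
        accepted++;
      } else {
        // undo
        m[d2] -= 1.0; m[d1] -= 1.0; m[c2] += 1.0; m[c1] += 1.0;
      }
    }
    (void)stat_here;
    if (step >= demem) {
      long s = step - demem;
      int b = (int)(s / iter_per_batch);
      prob[b] += (logw <= logw_obs + tol) ? 1.0 : 0.0;
      def[b]  += (H <= H_obs) ? 1.0 : 0.0;
      exc[b]  += (H >= H_obs) ? 1.0 : 0.0;
      if (keep_trace) trace[s] = H;
    }
  }
  for (int b = 0; b < batches; ++b) {
    prob[b] /= iter_per_batch;
    def[b] /= iter_per_batch;
    exc[b] /= iter_per_batch;
  }
  return List::create(_["prob"] = prob, _["deficit"] = def,
                      _["excess"] = exc, _["H_trace"] = trace,
                      _["accept_rate"] =
                        proposed ? (double)accepted / proposed : 0.0);
}
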