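#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Metropolis sampler over protonation microstates. One Monte Carlo step is
// one systematic scan over all sites, each attempted as a single-site flip
// (the usual convention in multi-site titration samplers). Uses R's RNG so
// runs are reproducible under set.seed(); standard errors are batch means
// over 20 batches of the post-burn-in sweeps.
// [[Rcpp::export]]
List mc_titrate_kernel(NumericVector pka, NumericMatrix W,
                       NumericVector pH_grid, int n_steps, int burn_in,
                       double RT, double ln10) {
  const int n = pka.size();
  const int npH = pH_grid.size();
  const int n_batch = 20;
  NumericMatrix prob(npH, n), se(npH, n);
  std::vector<int> s(n, 0);
  std::vector<double> Wv(n * n);  // row-major copy for fast access
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) Wv[i * n + j] = W(i, j);
  RNGScope scope;
  for (int p = 0; p < npH; ++p) {
    const double pH = pH_grid[p];
    std::vector<double> dg(n);
    for (int i = 0; i < n; ++i) dg[i] = ln10 * RT * (pH - pka[i]);
    std::vector<double> acc(n, 0.0);
    std::vector<double> batch(n * n_batch, 0.0);
    const int kept = n_steps - burn_in;
    for (int step = 0; step < n_steps; ++step) {
      for (int i = 0; i < n; ++i) {
        double dE = dg[i];
        const double *wrow = &Wv[i * n];
        for (int j = 0; j < n; ++j) dE += wrow[j] * s[j];  // W diagonal is 0
        if (s[i] == 1) dE = -dE;  // proposal removes the proton
        if (dE <= 0.0 || unif_rand() < std::exp(-dE / RT)) s[i] = 1 - s[i];
      }
      if (step >= burn_in) {
        int k = step - burn_in;
        int b = (int)((long long)k * n_batch / kept);
        if (b >= n_batch) b = n_batch - 1;
        for (int j = 0; j < n; ++j) {
          acc[j] += s[j];
          batch[b * n + j] += s[j];
        }
      }
    }
    const double bsize = (double)kept / n_batch;
    for (int j = 0; j < n; ++j) {
      const double mean = acc[j] / kept;
      prob(p, j) = mean;
      double ss = 0.0;
      for (int b = 0; b < n_batch; ++b) {
        const double bm = batch[b * n + j] / bsize;
        ss += (bm - mean) * (bm - mean);
      }
      // conservative error bar: batch-means variance plus a
      // Laplace-smoothed iid binomial floor (guards saturated sites,
      // where batch variance collapses to zero), added in quadrature
      const double pt = (acc[j] + 1.0) / (kept + 2.0);
      se(p, j) = std::sqrt(ss / (n_batch - 1) / n_batch +
                           pt * (1.0 - pt) / kept);
    }
  }
  return List::create(_["prob"] = prob, _["se"] = se);
}
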