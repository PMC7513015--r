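#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for a log-linear binary model with arbitrary-order features.
// One "sample" is one full sweep over sites in fixed order 1..N; the R
// wrapper handles seeding via set.seed(), and R's RNG is used here so runs
// are reproducible.
// features: list of 1-based integer index vectors; theta: one value each.
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(int n_neurons, List features,
                               NumericVector theta, int n_samples,
                               int burn_in, int thin) {
  int n_feat = features.size();
  if (thin < 1) thin = 1;

  // per-site list of (feature id, indices of the *other* members)
  std::vector<std::vector<int>> site_feats(n_neurons);
  std::vector<std::vector<int>> feat_idx(n_feat);
  for (int k = 0; k < n_feat; ++k) {
    IntegerVector f = features[k];
    for (int j = 0; j < f.size(); ++j) {
      int site = f[j] - 1;
      feat_idx[k].push_back(site);
      site_feats[site].push_back(k);
    }
  }

  std::vector<int> x(n_neurons, 0);
  IntegerMatrix out(n_samples, n_neurons);
  RNGScope scope;

  int total_sweeps = burn_in + n_samples * thin;
  int kept = 0;
  for (int sweep = 0; sweep < total_sweeps && kept < n_samples; ++sweep) {
    for (int i = 0; i < n_neurons; ++i) {
      double delta = 0.0;
      const std::vector<int>& sf = site_feats[i];
      for (size_t a = 0; a < sf.size(); ++a) {
        int k = sf[a];
        const std::vector<int>& idx = feat_idx[k];
        int prod = 1;
        for (size_t b = 0; b < idx.size(); ++b) {
          int j = idx[b];
          if (j == i) continue;
          if (x[j] == 0) { prod = 0; break; }
        }
        if (prod) delta += theta[k];
      }
      double p1 = 1.0 / (1.0 + std::exp(-delta));
      x[i] = (unif_rand() < p1) ? 1 : 0;
    }
    if (sweep >= burn_in && ((sweep - burn_in) % thin == 0)) {
      for (int i = 0; i < n_neurons; ++i) out(kept, i) = x[i];
      ++kept;
    }
  }
  return out;
}
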