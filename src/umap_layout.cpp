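#include <Rcpp.h>
using namespace Rcpp;

// Stochastic cross-entropy layout for a fuzzy neighbourhood graph.
// Edges are sampled according to their membership weight (via the
// epochs_per_sample schedule); each attractive update is followed by
// negative_sample_rate repulsive updates against uniformly sampled
// vertices.  Low-dimensional similarity is 1/(1 + a * d^(2b)).
// Uses R's RNG so results are reproducible under set.seed().
// Y is modified in place (n x d, column-major).

static inline double clamp4(double x) {
  if (x > 4.0) return 4.0;
  if (x < -4.0) return -4.0;
  return x;
}

// [[Rcpp::export]]
void optimize_umap_layout(NumericMatrix Y, IntegerVector head,
                          IntegerVector tail,
                          NumericVector epochs_per_sample, int n_epochs,
                          double a, double b, double gamma,
                          double initial_alpha,
                          int negative_sample_rate) {
  const int n = Y.nrow();
  const int dim = Y.ncol();
  const int n_edges = head.size();

  std::vector<double> epoch_of_next_sample(epochs_per_sample.begin(),
                                           epochs_per_sample.end());
  std::vector<double> eons(n_edges);
  for (int e = 0; e < n_edges; ++e)
    eons[e] = epochs_per_sample[e] / negative_sample_rate;
  std::vector<double> epoch_of_next_negative_sample(eons);

  double* y = REAL(Y);

  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    double alpha =
        initial_alpha * (1.0 - (double)(epoch - 1) / (double)n_epochs);
    for (int e = 0; e < n_edges; ++e) {
      if (epoch_of_next_sample[e] > epoch) continue;
      int i = head[e];
      int j = tail[e];
      // attractive update, moving both endpoints
      double d2 = 0.0;
      for (int c = 0; c < dim; ++c) {
        double diff = y[i + c * n] - y[j + c * n];
        d2 += diff * diff;
      }
      if (d2 > 0.0) {
        double grad_coeff =
            (-2.0 * a * b * std::pow(d2, b - 1.0)) /
            (a * std::pow(d2, b) + 1.0);
        for (int c = 0; c < dim; ++c) {
          double diff = y[i + c * n] - y[j + c * n];
          double g = clamp4(grad_coeff * diff);
          y[i + c * n] += alpha * g;
          y[j + c * n] -= alpha * g;
        }
      }
      epoch_of_next_sample[e] += epochs_per_sample[e];

      int n_neg = (int)((epoch - epoch_of_next_negative_sample[e]) /
                        eons[e]);
      for (int p = 0; p < n_neg; ++p) {
        int k = (int)(unif_rand() * n);
        if (k >= n) k = n - 1;
        if (k == i) continue;
        double dn2 = 0.0;
        for (int c = 0; c < dim; ++c) {
          double diff = y[i + c * n] - y[k + c * n];
          dn2 += diff * diff;
        }
        double grad_coeff = 0.0;
        if (dn2 > 0.0)
          grad_coeff = (2.0 * gamma * b) /
                       ((0.001 + dn2) * (a * std::pow(dn2, b) + 1.0));
        for (int c = 0; c < dim; ++c) {
          double diff = y[i + c * n] - y[k + c * n];
          double g = (grad_coeff > 0.0) ? clamp4(grad_coeff * diff) : 4.0;
          y[i + c * n] += alpha * g;
        }
      }
      epoch_of_next_negative_sample[e] += n_neg * eons[e];
    }
  }
}
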