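#include <Rcpp.h>
using namespace Rcpp;

// Online SOM training. `order` holds 0-based row indices of `data`, one per
// update step (passes * n rows, pre-shuffled in R under the caller's seed).
// Learning rate and neighborhood radius both decay linearly over all steps.
// The neighborhood is a Gaussian over Chebyshev distance on the node grid.
// [[Rcpp::export]]
NumericMatrix som_train_cpp(const NumericMatrix& data,
                            NumericMatrix weights,
                            const IntegerVector& order,
                            int grid_rows, int grid_cols,
                            double alpha_start, double alpha_end,
                            double radius_start, double radius_end) {
  const int m = data.ncol();
  const int n_nodes = weights.nrow();
  const R_xlen_t T = order.size();

  // grid coordinates of each node, row-major: node k -> (k / cols, k % cols)
  std::vector<int> gr(n_nodes), gc(n_nodes);
  for (int k = 0; k < n_nodes; ++k) {
    gr[k] = k / grid_cols;
    gc[k] = k % grid_cols;
  }

  for (R_xlen_t t = 0; t < T; ++t) {
    double frac = (T > 1) ? (double)t / (double)(T - 1) : 0.0;
    double alpha = alpha_start + (alpha_end - alpha_start) * frac;
    double radius = radius_start + (radius_end - radius_start) * frac;
    if (radius < 1e-9) radius = 1e-9;
    int i = order[t];

    // best-matching unit, ties broken by lowest node id
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < n_nodes; ++k) {
      double d = 0.0;
      for (int j = 0; j < m; ++j) {
        double diff = data(i, j) - weights(k, j);
        d += diff * diff;
      }
      if (d < best) { best = d; bmu = k; }
    }

    double denom = 2.0 * radius * radius;
    for (int k = 0; k < n_nodes; ++k) {
      int dr = std::abs(gr[k] - gr[bmu]);
      int dc = std::abs(gc[k] - gc[bmu]);
      int dch = dr > dc ? dr : dc;
      double h = std::exp(-(double)(dch * dch) / denom);
      if (h < 1e-12) continue;
      double ah = alpha * h;
      for (int j = 0; j < m; ++j)
        weights(k, j) += ah * (data(i, j) - weights(k, j));
    }
  }
  return weights;
}

// Round every value to the nearest single-precision float. Raw marker
// images are 32-bit floats; normalized ratios carry no information below
// that precision, and quantizing makes the clustering input invariant to
// global intensity rescaling at machine precision.
// [[Rcpp::export]]
NumericMatrix round_float32_cpp(const NumericMatrix& x) {
  NumericMatrix out(x.nrow(), x.ncol());
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (double)(float)x[i];
  return out;
}

// Nearest-node assignment (squared Euclidean), ties -> lowest node id.
// Returns 1-based node ids.
// [[Rcpp::export]]
IntegerVector som_assign_cpp(const NumericMatrix& data,
                             const NumericMatrix& weights) {
  const int n = data.nrow(), m = data.ncol(), n_nodes = weights.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < n_nodes; ++k) {
      double d = 0.0;
      for (int j = 0; j < m; ++j) {
        double diff = data(i, j) - weights(k, j);
        d += diff * diff;
      }
      if (d < best) { best = d; bmu = k; }
    }
    out[i] = bmu + 1;
  }
  return out;
}
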