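#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Exact k-nearest-neighbour search in feature space (squared Euclidean
// distance), chunked so the full N x N distance matrix is never held.
// The query pixel itself is always the first neighbour; the remaining
// k - 1 slots take the smallest distances with ties broken by lower
// pixel index. Returns 1-based neighbour indices and squared distances,
// each N x k.
// [[Rcpp::export]]
List knn_search(const arma::mat& F, int k, int chunk = 1024) {
  const int n = F.n_rows;
  if (k < 1 || k > n) stop("k must be between 1 and the number of pixels");
  IntegerMatrix idx(n, k);
  NumericMatrix d2(n, k);
  arma::vec norms = arma::sum(arma::square(F), 1);

  std::vector<std::pair<double, int>> cand;
  cand.reserve(n);

  for (int start = 0; start < n; start += chunk) {
    const int stop_ = std::min(start + chunk, n);
    arma::mat block = F.rows(start, stop_ - 1) * F.t();  // B x N
    for (int r = start; r < stop_; ++r) {
      const int br = r - start;
      cand.clear();
      for (int j = 0; j < n; ++j) {
        if (j == r) continue;
        double d = norms[r] + norms[j] - 2.0 * block(br, j);
        if (d < 0) d = 0;
        cand.push_back(std::make_pair(d, j));
      }
      const int m = k - 1;
      if (m > 0) {
        std::partial_sort(cand.begin(), cand.begin() + m, cand.end());
        // partial_sort on pair<double,int> orders ties by index already
      }
      idx(r, 0) = r + 1;
      d2(r, 0) = 0.0;
      for (int q = 0; q < m; ++q) {
        idx(r, q + 1) = cand[q].second + 1;
        d2(r, q + 1) = cand[q].first;
      }
    }
  }
  return List::create(_["idx"] = idx, _["d2"] = d2);
}
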