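#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-time-warping alignment cost between two equal- or unequal-length
// series. Local cost |a-b|; step = 1 gives the unweighted recursion
// D(i,j) = d(i,j) + min(D(i-1,j-1), D(i-1,j), D(i,j-1)) (each cell's cost
// counted once, equal to the cheapest monotone lattice path), step = 2 the
// symmetric2 pattern with diagonal weight 2. window >= 0 applies a
// Sakoe-Chiba band; window < 0 means unconstrained.
static double dtw_pair(const double* x, int nx, const double* y, int ny,
                       int step, int window) {
  const double INF = R_PosInf;
  std::vector<double> prev(ny + 1, INF), cur(ny + 1, INF);
  prev[0] = 0.0;
  for (int i = 1; i <= nx; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int jlo = 1, jhi = ny;
    if (window >= 0) {
      jlo = std::max(1, i - window);
      jhi = std::min(ny, i + window);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double d = std::fabs(x[i - 1] - y[j - 1]);
      double diag = prev[j - 1] + (step == 2 ? 2.0 * d : d);
      double up = prev[j] + d;
      double left = cur[j - 1] + d;
      double best = diag;
      if (up < best) best = up;
      if (left < best) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[ny];
}

// [[Rcpp::export(name = ".dtw_pairwise")]]
NumericMatrix dtw_pairwise_cpp(NumericMatrix x, int step, int window) {
  int n = x.nrow(), m = x.ncol();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    std::vector<double> xi(m);
    for (int k = 0; k < m; ++k) xi[k] = x(i, k);
    for (int j = i + 1; j < n; ++j) {
      std::vector<double> xj(m);
      for (int k = 0; k < m; ++k) xj[k] = x(j, k);
      double d = dtw_pair(xi.data(), m, xj.data(), m, step, window);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".dtw_single")]]
double dtw_single_cpp(NumericVector x, NumericVector y, int step, int window) {
  return dtw_pair(x.begin(), x.size(), y.begin(), y.size(), step, window);
}
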