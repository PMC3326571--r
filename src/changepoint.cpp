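#include <Rcpp.h>
using namespace Rcpp;

// Change-point scan statistic combining:
//  (a) the single-split scaled CUSUM
//        stat_k = |S_k| / sqrt(k (n-k) / n),  S_k = sum_{i<=k} (x_i - mean),
//      equivalent (up to the residual SD) to the two-sample t statistic and
//      exact at the edge of a clean step; and
//  (b) a windowed arc scan, max over window lengths w on a geometric grid
//      and all offsets i of |S_{i+w} - S_i| / sqrt(w (n-w) / n),
//      which restores sensitivity to short interior segments (spikes) that
//      the single-split statistic dilutes.
// Both are scale-free, so permutation p-values need no variance estimate.
// `argmax` receives the best single-split location (used for cutting).
static double cbs_scan(const std::vector<double> &x, int min_seg,
                       int *argmax) {
  int n = (int)x.size();
  if (argmax) *argmax = -1;
  if (n < 2 * min_seg) return 0.0;
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  // prefix sums of centered values
  std::vector<double> S(n + 1, 0.0);
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + (x[i] - mean);
  double best = 0.0;
  int bestk = -1;
  for (int k = min_seg; k <= n - min_seg; ++k) {
    double denom = std::sqrt((double)k * (double)(n - k) / (double)n);
    double stat = std::fabs(S[k]) / denom;
    if (stat > best) { best = stat; bestk = k; }
  }
  if (argmax) *argmax = bestk;
  double overall = best;
  // geometric window grid (x1.5), windows up to n/2
  for (double wf = min_seg; wf <= n / 2; wf *= 1.5) {
    int w = (int)wf;
    double denom = std::sqrt((double)w * (double)(n - w) / (double)n);
    for (int i = 1; i + w < n; ++i) {  // interior arcs only
      double stat = std::fabs(S[i + w] - S[i]) / denom;
      if (stat > overall) overall = stat;
    }
  }
  return overall;
}

//' @noRd
// [[Rcpp::export(name = ".cusum_max")]]
List cusum_max(NumericVector x, int min_seg) {
  std::vector<double> v(x.begin(), x.end());
  int k = -1;
  double stat = cbs_scan(v, min_seg, &k);
  return List::create(_["stat"] = stat, _["k"] = k);
}

// Permutation p-value for the scan statistic, using R's RNG so that
// set.seed() in R makes results reproducible. Early stopping: once the
// exceedance count alone guarantees the final p-value exceeds `alpha`,
// the significance call is settled and a conservative estimate of p is
// returned (exceedances so far against the full permutation count).
//' @noRd
// [[Rcpp::export(name = ".cusum_perm_pvalue")]]
double cusum_perm_pvalue(NumericVector x, int min_seg, double observed,
                         int nperm, double alpha) {
  int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  RNGScope scope;
  int exceed = 0;
  for (int b = 1; b <= nperm; ++b) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(v[i], v[j]);
    }
    double stat = cbs_scan(v, min_seg, NULL);
    if (stat >= observed) {
      ++exceed;
      if ((double)(exceed + 1) > alpha * (double)(nperm + 1)) {
        double p = (double)(exceed + 1) / (double)(nperm + 1);
        return p > 1.0 ? 1.0 : p;
      }
    }
  }
  return (double)(exceed + 1) / (double)(nperm + 1);
}

// Pooled permutation null for cohort G-scores. `contrib` holds one row per
// sample of non-negative per-probe score contributions; each permutation
// cyclically shifts every row by an independent random offset (preserving
// within-sample segment structure) and the per-probe column sums are pooled
// into the returned null distribution (length nperm * nprobes).
//' @noRd
// [[Rcpp::export(name = ".gscore_perm_null")]]
NumericVector gscore_perm_null(NumericMatrix contrib, int nperm) {
  int ns = contrib.nrow(), np = contrib.ncol();
  NumericVector out((R_xlen_t)nperm * np);
  std::vector<double> acc(np);
  RNGScope scope;
  R_xlen_t pos = 0;
  for (int b = 0; b < nperm; ++b) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int s = 0; s < ns; ++s) {
      int off = (int)(unif_rand() * np);
      if (off >= np) off = np - 1;
      for (int j = 0; j < np; ++j) {
        int jj = j + off;
        if (jj >= np) jj -= np;
        acc[jj] += contrib(s, j);
      }
    }
    for (int j = 0; j < np; ++j) out[pos++] = acc[j];
  }
  return out;
}
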