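#include <Rcpp.h>
using namespace Rcpp;

// Exact least-squares segmentation of a numeric signal into k contiguous
// pieces, for every k = 1..kmax.  Cost of a segment [i, j) is its residual
// sum of squares around the segment mean, computed in O(1) from prefix
// sums.  The full O(kmax * n^2) dynamic program is run: the RSS cost of a
// time-series segment is not Monge, so divide-and-conquer / SMAWK
// speedups are not valid and the quadratic scan is required for
// exactness (windowing keeps it affordable upstream).

static inline double seg_cost(const std::vector<double> &S,
                              const std::vector<double> &S2,
                              int i, int j) {
  // segment [i, j), j > i
  double s = S[j] - S[i];
  double q = S2[j] - S2[i];
  double rss = q - s * s / (double)(j - i);
  return rss > 0.0 ? rss : 0.0; // clamp tiny negative round-off
}

// [[Rcpp::export(name = ".segment_dp_cpp")]]
List segment_dp_cpp(NumericVector x, int kmax) {
  int n = x.size();
  if (n < 1) stop("empty signal");
  if (kmax < 1) stop("kmax must be >= 1");
  if (kmax > n) kmax = n;

  std::vector<double> S(n + 1, 0.0), S2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + x[i];
    S2[i + 1] = S2[i] + x[i] * x[i];
  }

  NumericVector rss(kmax);
  IntegerMatrix arg(kmax, n + 1);
  std::fill(arg.begin(), arg.end(), -1);

  std::vector<double> prev(n + 1, R_PosInf), cur(n + 1, R_PosInf);
  for (int j = 1; j <= n; ++j) prev[j] = seg_cost(S, S2, 0, j);
  rss[0] = prev[n];

  for (int k = 2; k <= kmax; ++k) {
    std::fill(cur.begin(), cur.end(), R_PosInf);
    for (int j = k; j <= n; ++j) {
      double best = R_PosInf;
      int besti = -1;
      for (int i = k - 1; i < j; ++i) {
        if (!R_finite(prev[i])) continue;
        double v = prev[i] + seg_cost(S, S2, i, j);
        if (v < best) { best = v; besti = i; }
      }
      cur[j] = best;
      arg(k - 1, j) = besti;
    }
    rss[k - 1] = cur[n];
    std::swap(prev, cur);
  }

  return List::create(_["rss"] = rss, _["arg"] = arg);
}

// Backtrack the changepoints (0-based segment start indices, excluding 0)
// for a given number of segments k.
// [[Rcpp::export(name = ".segment_backtrack_cpp")]]
IntegerVector segment_backtrack_cpp(IntegerMatrix arg, int n, int k) {
  std::vector<int> cps;
  int j = n;
  for (int level = k; level >= 2; --level) {
    int i = arg(level - 1, j);
    if (i < 0) stop("internal error: broken backpointer");
    cps.push_back(i);
    j = i;
  }
  std::sort(cps.begin(), cps.end());
  return wrap(cps);
}
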