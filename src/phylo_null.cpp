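#include <Rcpp.h>
using namespace Rcpp;

// Abundance-weighted mean pairwise distance and mean nearest-taxon distance
// for a species profile w on a patristic distance matrix D, plus the
// tip-shuffling randomization null used for standardized effect sizes.
// Weights are the per-species conservation counts of a module (or 1/0 for
// presence-only mode).

static void mpd_mntd_w(const NumericMatrix &D, const std::vector<double> &w,
                       const std::vector<int> &present,
                       double &mpd, double &mntd) {
  int m = present.size();
  mpd = NA_REAL;
  mntd = NA_REAL;
  if (m < 2) return;
  double num = 0.0, den = 0.0, nnum = 0.0, nden = 0.0;
  for (int a = 0; a < m; ++a) {
    int i = present[a];
    double dmin = R_PosInf;
    for (int b = 0; b < m; ++b) {
      if (a == b) continue;
      int j = present[b];
      double d = D(i, j);
      if (d < dmin) dmin = d;
      if (b > a) {
        num += d * w[i] * w[j];
        den += w[i] * w[j];
      }
    }
    nnum += w[i] * dmin;
    nden += w[i];
  }
  mpd = num / den;
  mntd = nnum / nden;
}

// [[Rcpp::export(name = ".mpd_mntd_cpp")]]
NumericVector mpd_mntd_cpp(NumericMatrix D, NumericVector w) {
  int S = D.nrow();
  std::vector<double> wv(w.begin(), w.end());
  std::vector<int> present;
  for (int i = 0; i < S; ++i) if (wv[i] > 0) present.push_back(i);
  double mpd, mntd;
  mpd_mntd_w(D, wv, present, mpd, mntd);
  return NumericVector::create(_["mpd"] = mpd, _["mntd"] = mntd);
}

// Null distribution: shuffle the profile values across tips (the tree and
// its distances stay fixed), nrand times.  Uses R's RNG so results follow
// set.seed().
// [[Rcpp::export(name = ".mpd_mntd_null_cpp")]]
NumericMatrix mpd_mntd_null_cpp(NumericMatrix D, NumericVector w, int nrand) {
  int S = D.nrow();
  NumericMatrix out(nrand, 2);
  std::vector<double> wv(w.begin(), w.end());
  std::vector<int> present;
  RNGScope scope;
  for (int r = 0; r < nrand; ++r) {
    // Fisher-Yates shuffle of wv
    for (int i = S - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(wv[i], wv[j]);
    }
    present.clear();
    for (int i = 0; i < S; ++i) if (wv[i] > 0) present.push_back(i);
    double mpd, mntd;
    mpd_mntd_w(D, wv, present, mpd, mntd);
    out(r, 0) = mpd;
    out(r, 1) = mntd;
  }
  return out;
}
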