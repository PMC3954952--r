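#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// One-variable stepwise-constant (decision stump) classifier.
//
// Candidate thresholds are -Inf, the midpoints between consecutive sorted
// unique values, and +Inf. Direction "old-above" predicts old for
// value > threshold; "old-below" predicts old for value < threshold.
// Ties in training error are broken deterministically: lowest threshold
// first, then old-above before old-below.

struct Stump {
  double threshold;
  bool old_above;
  double error;  // misclassified fraction on the fitting data
};

static Stump fit_stump_core(const std::vector<double>& x,
                            const std::vector<int>& old) {
  const int n = (int)x.size();
  int n_old = 0;
  for (int i = 0; i < n; ++i) n_old += old[i];
  const int n_young = n - n_old;

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  // candidate cut position i in [0, n]: threshold lies between sorted
  // value i-1 and i; valid only at i = 0, i = n, or where the values differ.
  Stump best;
  best.threshold = R_NegInf;
  best.old_above = true;
  best.error = 1.0 + 1.0 / std::max(n, 1);  // worse than any real error

  int old_left = 0;  // old among the first i sorted values
  for (int i = 0; i <= n; ++i) {
    bool boundary = (i == 0) || (i == n) ||
                    (x[idx[i - 1]] != x[idx[i]]);
    if (boundary) {
      double thr;
      if (i == 0) thr = R_NegInf;
      else if (i == n) thr = R_PosInf;
      else thr = 0.5 * (x[idx[i - 1]] + x[idx[i]]);
      int young_left = i - old_left;
      // old-above: misclassified = old at/below + young above
      double err_above = (double)(old_left + (n_young - young_left)) / n;
      double err_below = (double)(young_left + (n_old - old_left)) / n;
      if (err_above < best.error) {
        best.threshold = thr; best.old_above = true; best.error = err_above;
      }
      if (err_below < best.error) {
        best.threshold = thr; best.old_above = false; best.error = err_below;
      }
    }
    if (i < n) old_left += old[idx[i]];
  }
  return best;
}

static inline bool predict_old(const Stump& s, double v) {
  return s.old_above ? (v > s.threshold) : (v < s.threshold);
}

// [[Rcpp::export(name = ".stump_fit_cpp")]]
List stump_fit_cpp(NumericVector x, LogicalVector old) {
  if (x.size() != old.size()) stop("length mismatch");
  std::vector<double> xv(x.begin(), x.end());
  std::vector<int> ov(old.begin(), old.end());
  Stump s = fit_stump_core(xv, ov);
  return List::create(_["threshold"] = s.threshold,
                      _["direction"] = s.old_above ? "old-above" : "old-below",
                      _["training_error"] = s.error);
}

static double loocv_core(const std::vector<double>& x,
                         const std::vector<int>& old) {
  const int n = (int)x.size();
  std::vector<double> xr(n - 1);
  std::vector<int> or_(n - 1);
  int miss = 0;
  for (int i = 0; i < n; ++i) {
    int k = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      xr[k] = x[j];
      or_[k] = old[j];
      ++k;
    }
    Stump s = fit_stump_core(xr, or_);
    if (predict_old(s, x[i]) != (old[i] == 1)) ++miss;
  }
  return (double)miss / n;
}

// [[Rcpp::export(name = ".stump_loocv_cpp")]]
double stump_loocv_cpp(NumericVector x, LogicalVector old) {
  if (x.size() != old.size()) stop("length mismatch");
  std::vector<double> xv(x.begin(), x.end());
  std::vector<int> ov(old.begin(), old.end());
  return loocv_core(xv, ov);
}

// [[Rcpp::export(name = ".stump_screen_cpp")]]
DataFrame stump_screen_cpp(NumericMatrix m, LogicalVector old) {
  const int nr = m.nrow(), nc = m.ncol();
  if (old.size() != nc) stop("group length mismatch");
  NumericVector threshold(nr), train_err(nr), cv_err(nr);
  CharacterVector direction(nr);
  LogicalVector universal(nr);
  std::vector<double> xv(nc);
  std::vector<int> ov(old.begin(), old.end());
  for (int r = 0; r < nr; ++r) {
    double max_y = R_NegInf, min_y = R_PosInf;
    double max_o = R_NegInf, min_o = R_PosInf;
    for (int c = 0; c < nc; ++c) {
      xv[c] = m(r, c);
      if (ov[c]) { max_o = std::max(max_o, xv[c]); min_o = std::min(min_o, xv[c]); }
      else { max_y = std::max(max_y, xv[c]); min_y = std::min(min_y, xv[c]); }
    }
    Stump s = fit_stump_core(xv, ov);
    threshold[r] = s.threshold;
    direction[r] = s.old_above ? "old-above" : "old-below";
    train_err[r] = s.error;
    cv_err[r] = loocv_core(xv, ov);
    universal[r] = (max_y < min_o) || (max_o < min_y);
  }
  return DataFrame::create(_["threshold"] = threshold,
                           _["direction"] = direction,
                           _["training_error"] = train_err,
                           _["cv_error"] = cv_err,
                           _["is_universal"] = universal,
                           _["stringsAsFactors"] = false);
}
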