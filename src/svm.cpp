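#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// L2-regularized L1-loss linear SVM with per-sample costs, solved in the
// dual by cyclic coordinate descent (Hsieh et al., ICML 2008). The bias is
// handled as an augmented constant feature of value 1. Deterministic: fixed
// cyclic update order, no randomization.
//
// Xt: p x n matrix, one column per sample (standardized by the caller).
// y: +1 / -1 labels. Ci: per-sample cost (C * balanced weight).
static void svm_dual_cd(const double* Xt, int p, int n,
                        const int* y, const double* Ci,
                        double eps, int max_passes,
                        std::vector<double>& w, double& b) {
  std::vector<double> alpha(n, 0.0), qii(n);
  w.assign(p, 0.0);
  b = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* xi = Xt + (size_t)i * p;
    double s = 1.0; // bias feature
    for (int j = 0; j < p; ++j) s += xi[j] * xi[j];
    qii[i] = s;
  }
  for (int pass = 0; pass < max_passes; ++pass) {
    double pgmax = -1e300, pgmin = 1e300;
    for (int i = 0; i < n; ++i) {
      const double* xi = Xt + (size_t)i * p;
      double dot = b;
      for (int j = 0; j < p; ++j) dot += w[j] * xi[j];
      double G = y[i] * dot - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0) PG = std::min(G, 0.0);
      else if (alpha[i] >= Ci[i]) PG = std::max(G, 0.0);
      if (PG > pgmax) pgmax = PG;
      if (PG < pgmin) pgmin = PG;
      if (std::fabs(PG) > 1e-12) {
        double a_new = alpha[i] - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > Ci[i]) a_new = Ci[i];
        double d = (a_new - alpha[i]) * y[i];
        if (d != 0.0) {
          for (int j = 0; j < p; ++j) w[j] += d * xi[j];
          b += d;
          alpha[i] = a_new;
        }
      }
    }
    if (pgmax - pgmin < eps) break;
  }
}

// [[Rcpp::export(name = ".cppSvmFit")]]
List cppSvmFit(NumericMatrix Xt, IntegerVector y, NumericVector Ci,
               double eps = 0.1, int maxPasses = 200) {
  int p = Xt.nrow(), n = Xt.ncol();
  std::vector<double> w;
  double b;
  svm_dual_cd(Xt.begin(), p, n, y.begin(), Ci.begin(), eps, maxPasses, w, b);
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["b"] = b);
}

// Recursive feature elimination: repeatedly fit the SVM on the remaining
// features and drop the `step` features with smallest |coefficient|, where
// step = max(1, floor(frac * remaining)) while more than `keepExact`
// features remain, then 1 at a time. Ties on |coefficient| are broken by
// `tieOrder` (the lexicographic rank of each feature name): among equal
// coefficients the lexicographically later feature is eliminated first, so
// the final ranking lists tied features in name order.
//
// Returns the elimination order (1-based feature indices, first eliminated
// first); the ranking is its reverse.
// [[Rcpp::export(name = ".cppRfeRank")]]
IntegerVector cppRfeRank(NumericMatrix Xt, IntegerVector y, NumericVector Ci,
                         IntegerVector tieOrder, int keepExact = 64,
                         double frac = 0.1, double eps = 0.1,
                         int maxPasses = 200, int fixedStep = 0) {
  int p = Xt.nrow(), n = Xt.ncol();
  std::vector<int> active(p);
  for (int j = 0; j < p; ++j) active[j] = j;
  std::vector<int> eliminated;
  eliminated.reserve(p);
  std::vector<double> sub, w;
  double b;
  while (!active.empty()) {
    int pr = (int)active.size();
    if (pr == 1 && fixedStep <= 0) {
      eliminated.push_back(active[0]);
      break;
    }
    sub.resize((size_t)pr * n);
    for (int i = 0; i < n; ++i) {
      const double* col = &Xt(0, i);
      double* dst = &sub[(size_t)i * pr];
      for (int j = 0; j < pr; ++j) dst[j] = col[active[j]];
    }
    svm_dual_cd(sub.data(), pr, n, y.begin(), Ci.begin(), eps, maxPasses,
                w, b);
    int step;
    if (fixedStep > 0) {
      step = std::min(fixedStep, pr);
    } else {
      step = (pr > keepExact) ? std::max(1, (int)std::floor(frac * pr)) : 1;
      if (pr > keepExact && pr - step < keepExact) step = pr - keepExact;
      if (step >= pr) step = pr - 1;
      if (step < 1) step = 1;
    }
    // order active features by (|w|, tieOrder descending)
    std::vector<int> idx(pr);
    for (int j = 0; j < pr; ++j) idx[j] = j;
    std::stable_sort(idx.begin(), idx.end(), [&](int a_, int b_) {
      double wa = std::fabs(w[a_]), wb = std::fabs(w[b_]);
      if (wa != wb) return wa < wb;
      return tieOrder[active[a_]] > tieOrder[active[b_]];
    });
    std::vector<int> drop(idx.begin(), idx.begin() + step);
    for (int j : drop) eliminated.push_back(active[j]);
    std::sort(drop.begin(), drop.end());
    std::vector<int> keep;
    keep.reserve(pr - step);
    size_t di = 0;
    for (int j = 0; j < pr; ++j) {
      if (di < drop.size() && drop[di] == j) { ++di; continue; }
      keep.push_back(active[j]);
    }
    active.swap(keep);
  }
  IntegerVector out(eliminated.size());
  for (size_t j = 0; j < eliminated.size(); ++j) out[j] = eliminated[j] + 1;
  return out;
}
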