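#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Random Ferns: an ensemble of fixed-depth "ferns". A fern of depth D applies
// the same D split rules (feature, threshold) to every path, yielding 2^D
// leaves holding additively smoothed log class-probability vectors of the
// in-bag samples routed there. Splits are fully random: feature uniform over
// all genes, threshold uniform between the in-bag min and max of that gene.
// All randomness comes from R's RNG (callers set.seed beforehand).

static inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static inline int leaf_of(const NumericMatrix &X, int i,
                          const int *feat, const double *thr, int D) {
  int leaf = 0;
  for (int d = 0; d < D; ++d)
    leaf = (leaf << 1) | (X(i, feat[d]) > thr[d] ? 1 : 0);
  return leaf;
}

// [[Rcpp::export]]
List cpp_train_ferns(NumericMatrix X, IntegerVector y, int n_classes,
                     int depth, int n_ferns) {
  const int n = X.nrow(), p = X.ncol(), D = depth, K = n_ferns;
  const int L = 1 << D;
  IntegerMatrix feat(K, D);
  NumericMatrix thr(K, D);
  NumericVector logp(((double)K) * L * n_classes);
  List oob(K);
  std::vector<int> bag(n), inbag(n);

  for (int k = 0; k < K; ++k) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      bag[i] = rand_int(n);
      inbag[bag[i]]++;
    }
    int fk[8];
    double tk[8];
    for (int d = 0; d < D; ++d) {
      int f = rand_int(p);
      double lo = R_PosInf, hi = R_NegInf;
      for (int i = 0; i < n; ++i) {
        if (!inbag[i]) continue;
        double v = X(i, f);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      double t = lo + unif_rand() * (hi - lo);
      feat(k, d) = f;
      thr(k, d) = t;
      fk[d] = f;
      tk[d] = t;
    }
    // smoothed class counts per leaf (Laplace +1 avoids log 0)
    std::vector<double> cnt((size_t)L * n_classes, 1.0);
    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) continue;
      int leaf = leaf_of(X, i, fk, tk, D);
      cnt[(size_t)leaf * n_classes + y[i]] += inbag[i];
    }
    size_t base = (size_t)k * L * n_classes;
    for (int l = 0; l < L; ++l) {
      double tot = 0;
      for (int c = 0; c < n_classes; ++c) tot += cnt[(size_t)l * n_classes + c];
      for (int c = 0; c < n_classes; ++c)
        logp[base + (size_t)l * n_classes + c] =
          std::log(cnt[(size_t)l * n_classes + c] / tot);
    }
    std::vector<int> ob;
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) ob.push_back(i + 1); // 1-based for R
    oob[k] = IntegerVector(ob.begin(), ob.end());
  }
  return List::create(_["feat"] = feat, _["thr"] = thr, _["logp"] = logp,
                      _["oob"] = oob);
}

// [[Rcpp::export]]
NumericMatrix cpp_ferns_scores(IntegerMatrix feat, NumericMatrix thr,
                               NumericVector logp, int depth, int n_classes,
                               NumericMatrix X) {
  const int n = X.nrow(), K = feat.nrow(), D = depth, L = 1 << D;
  NumericMatrix scores(n, n_classes);
  int fk[8];
  double tk[8];
  for (int k = 0; k < K; ++k) {
    for (int d = 0; d < D; ++d) {
      fk[d] = feat(k, d);
      tk[d] = thr(k, d);
    }
    size_t base = (size_t)k * L * n_classes;
    for (int i = 0; i < n; ++i) {
      int leaf = leaf_of(X, i, fk, tk, D);
      for (int c = 0; c < n_classes; ++c)
        scores(i, c) += logp[base + (size_t)leaf * n_classes + c];
    }
  }
  return scores;
}

// OOB permutation importance on the correct-class probability scale.
// For every fern and every gene used in its splits: mean over the fern's OOB
// samples of P(correct class) minus the same after permuting that gene's
// values among those OOB samples (one permutation). A gene's score is the
// mean contribution over the ferns that use it; genes used nowhere score 0.
// Probabilities (not their logs) keep every contribution bounded in [-1, 1].
// [[Rcpp::export]]
NumericVector cpp_ferns_importance(IntegerMatrix feat, NumericMatrix thr,
                                   NumericVector logp, List oob, int depth,
                                   int n_classes, NumericMatrix X,
                                   IntegerVector y) {
  const int p = X.ncol(), K = feat.nrow(), D = depth, L = 1 << D;
  NumericVector acc(p), cnt(p);
  int fk[8];
  double tk[8];
  for (int k = 0; k < K; ++k) {
    IntegerVector ob = oob[k];
    const int m = ob.size();
    if (m == 0) continue; // fern with no OOB coverage contributes nothing
    for (int d = 0; d < D; ++d) {
      fk[d] = feat(k, d);
      tk[d] = thr(k, d);
    }
    size_t base = (size_t)k * L * n_classes;
    double b0 = 0;
    for (int j = 0; j < m; ++j) {
      int i = ob[j] - 1;
      int leaf = leaf_of(X, i, fk, tk, D);
      b0 += std::exp(logp[base + (size_t)leaf * n_classes + y[i]]);
    }
    b0 /= m;
    for (int d = 0; d < D; ++d) {
      int g = fk[d];
      bool seen = false; // each distinct gene once per fern
      for (int e = 0; e < d; ++e)
        if (fk[e] == g) { seen = true; break; }
      if (seen) continue;
      // permute this gene's values among the OOB samples (Fisher-Yates)
      std::vector<double> v(m);
      for (int j = 0; j < m; ++j) v[j] = X(ob[j] - 1, g);
      for (int j = m - 1; j > 0; --j)
        std::swap(v[j], v[rand_int(j + 1)]);
      double b1 = 0;
      for (int j = 0; j < m; ++j) {
        int i = ob[j] - 1;
        int leaf = 0;
        for (int d2 = 0; d2 < D; ++d2) {
          double x = (fk[d2] == g) ? v[j] : X(i, fk[d2]);
          leaf = (leaf << 1) | (x > tk[d2] ? 1 : 0);
        }
        b1 += std::exp(logp[base + (size_t)leaf * n_classes + y[i]]);
      }
      b1 /= m;
      acc[g] += b0 - b1;
      cnt[g] += 1;
    }
  }
  for (int g = 0; g < p; ++g)
    if (cnt[g] > 0) acc[g] /= cnt[g];
  return acc;
}
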