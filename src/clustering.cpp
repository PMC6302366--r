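#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Seeded RNG independent of R's RNG state so clustering results are a pure
// function of (data, K, seed) and never perturb user-level set.seed() streams.
typedef std::mt19937 rng_t;

// copy an R matrix (column-major) into a contiguous row-major buffer so the
// per-object inner loops below touch memory sequentially
static std::vector<double> to_rowmajor(const NumericMatrix& X) {
  int n = X.nrow(), S = X.ncol();
  std::vector<double> out((size_t)n * S);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < n; ++i) out[(size_t)i * S + s] = X(i, s);
  return out;
}

static inline double sqdist_ptr(const double* x, const double* c, int S) {
  double d = 0.0;
  for (int s = 0; s < S; ++s) {
    double v = x[s] - c[s];
    d += v * v;
  }
  return d;
}

// k-means++ seeding: first center uniform, subsequent centers with
// probability proportional to squared distance to the nearest chosen center.
static std::vector<double> kmeanspp_init(const std::vector<double>& X, int n,
                                         int S, int K, rng_t& rng) {
  std::vector<double> centers((size_t)K * S);
  std::uniform_int_distribution<int> unif(0, n - 1);
  int first = unif(rng);
  std::copy(&X[(size_t)first * S], &X[(size_t)first * S] + S, centers.begin());
  std::vector<double> d2(n);
  for (int k = 1; k < K; ++k) {
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
      double best = std::numeric_limits<double>::infinity();
      for (int c = 0; c < k; ++c)
        best = std::min(best, sqdist_ptr(&X[(size_t)i * S],
                                         &centers[(size_t)c * S], S));
      d2[i] = best;
      total += best;
    }
    int pick;
    if (total <= 0.0) {
      pick = unif(rng); // all points coincide with a center
    } else {
      std::uniform_real_distribution<double> u(0.0, total);
      double r = u(rng), cum = 0.0;
      pick = n - 1;
      for (int i = 0; i < n; ++i) {
        cum += d2[i];
        if (cum >= r) { pick = i; break; }
      }
    }
    std::copy(&X[(size_t)pick * S], &X[(size_t)pick * S] + S,
              centers.begin() + (size_t)k * S);
  }
  return centers;
}

// One Lloyd run from given centers; empty clusters are repaired by moving the
// point farthest from its assigned center into the empty cluster.
static double lloyd(const std::vector<double>& X, int n, int S, int K,
                    std::vector<double>& centers, std::vector<int>& labels,
                    int max_iter, double tol) {
  labels.assign(n, 0);
  double prev_wcss = std::numeric_limits<double>::infinity();
  double wcss = prev_wcss;
  for (int iter = 0; iter < max_iter; ++iter) {
    // assignment
    wcss = 0.0;
    for (int i = 0; i < n; ++i) {
      double best = std::numeric_limits<double>::infinity();
      int bk = 0;
      for (int k = 0; k < K; ++k) {
        double d = sqdist_ptr(&X[(size_t)i * S], &centers[(size_t)k * S], S);
        if (d < best) { best = d; bk = k; }
      }
      labels[i] = bk;
      wcss += best;
    }
    // empty-cluster repair
    std::vector<int> counts(K, 0);
    for (int i = 0; i < n; ++i) counts[labels[i]]++;
    for (int k = 0; k < K; ++k) {
      if (counts[k] == 0) {
        int far_i = -1;
        double far_d = -1.0;
        for (int i = 0; i < n; ++i) {
          if (counts[labels[i]] > 1) {
            double d = sqdist_ptr(&X[(size_t)i * S],
                                  &centers[(size_t)labels[i] * S], S);
            if (d > far_d) { far_d = d; far_i = i; }
          }
        }
        if (far_i >= 0) {
          counts[labels[far_i]]--;
          labels[far_i] = k;
          counts[k] = 1;
          std::copy(&X[(size_t)far_i * S], &X[(size_t)far_i * S] + S,
                    centers.begin() + (size_t)k * S);
        }
      }
    }
    // update
    std::vector<double> newc((size_t)K * S, 0.0);
    std::vector<int> cnt(K, 0);
    for (int i = 0; i < n; ++i) {
      cnt[labels[i]]++;
      double* c = &newc[(size_t)labels[i] * S];
      const double* x = &X[(size_t)i * S];
      for (int s = 0; s < S; ++s) c[s] += x[s];
    }
    for (int k = 0; k < K; ++k)
      if (cnt[k] > 0)
        for (int s = 0; s < S; ++s) newc[(size_t)k * S + s] /= cnt[k];
    centers = newc;
    if (std::isfinite(prev_wcss) &&
        prev_wcss - wcss <= tol * std::max(1.0, prev_wcss)) break;
    prev_wcss = wcss;
  }
  // final assignment/WCSS against converged centers
  wcss = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bk = 0;
    for (int k = 0; k < K; ++k) {
      double d = sqdist_ptr(&X[(size_t)i * S], &centers[(size_t)k * S], S);
      if (d < best) { best = d; bk = k; }
    }
    labels[i] = bk;
    wcss += best;
  }
  return wcss;
}

// [[Rcpp::export]]
List cpp_kmeans(NumericMatrix X, int K, int seed, int n_init = 10,
                int max_iter = 300, double tol = 1e-6) {
  int n = X.nrow(), S = X.ncol();
  if (K > n) stop("K (%d) exceeds the number of objects (%d)", K, n);
  std::vector<double> data = to_rowmajor(X);
  rng_t rng(static_cast<unsigned int>(seed));
  std::vector<int> best_labels;
  double best_wcss = std::numeric_limits<double>::infinity();
  for (int rep = 0; rep < n_init; ++rep) {
    std::vector<double> centers = kmeanspp_init(data, n, S, K, rng);
    std::vector<int> labels;
    double w = lloyd(data, n, S, K, centers, labels, max_iter, tol);
    if (w < best_wcss) {
      best_wcss = w;
      best_labels = labels;
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = best_labels[i] + 1;
  return List::create(_["labels"] = out, _["wcss"] = best_wcss);
}

// Martinetz-Schulten online neural gas. All prototypes adapt toward each
// presented sample with strength exp(-rank/lambda); eps and lambda decay
// exponentially from their initial to final values over epochs * n steps.
// [[Rcpp::export]]
List cpp_neural_gas(NumericMatrix X, int K, int seed,
                             int epochs = 100, double lambda0 = -1.0,
                             double lambda_final = 0.01, double eps0 = 0.5,
                             double eps_final = 0.005) {
  int n = X.nrow(), S = X.ncol();
  if (K > n) stop("K (%d) exceeds the number of objects (%d)", K, n);
  if (lambda0 <= 0.0) lambda0 = std::max(K / 2.0, 1e-8);
  std::vector<double> data = to_rowmajor(X);
  rng_t rng(static_cast<unsigned int>(seed));

  // init prototypes from K distinct data points
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::shuffle(idx.begin(), idx.end(), rng);
  std::vector<double> W((size_t)K * S);
  for (int k = 0; k < K; ++k)
    std::copy(&data[(size_t)idx[k] * S], &data[(size_t)idx[k] * S] + S,
              W.begin() + (size_t)k * S);

  long T = static_cast<long>(epochs) * n;
  long t = 0;
  std::vector<int> order(idx);
  std::vector<std::pair<double, int> > dists(K);
  double log_lambda_ratio = std::log(lambda_final / lambda0);
  double log_eps_ratio = std::log(eps_final / eps0);
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < n; ++oi, ++t) {
      int i = order[oi];
      const double* x = &data[(size_t)i * S];
      double frac = (T > 1) ? static_cast<double>(t) / (T - 1) : 1.0;
      double lambda = lambda0 * std::exp(log_lambda_ratio * frac);
      double eps = eps0 * std::exp(log_eps_ratio * frac);
      for (int k = 0; k < K; ++k)
        dists[k] = std::make_pair(sqdist_ptr(x, &W[(size_t)k * S], S), k);
      std::sort(dists.begin(), dists.end());
      for (int r = 0; r < K; ++r) {
        double h = eps * std::exp(-static_cast<double>(r) / lambda);
        if (h < 1e-12) break; // negligible update for all further ranks
        double* w = &W[(size_t)dists[r].second * S];
        for (int s = 0; s < S; ++s) w[s] += h * (x[s] - w[s]);
      }
    }
  }
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bk = 0;
    for (int k = 0; k < K; ++k) {
      double d = sqdist_ptr(&data[(size_t)i * S], &W[(size_t)k * S], S);
      if (d < best) { best = d; bk = k; }
    }
    labels[i] = bk + 1;
  }
  NumericMatrix proto(K, S);
  for (int k = 0; k < K; ++k)
    for (int s = 0; s < S; ++s) proto(k, s) = W[(size_t)k * S + s];
  return List::create(_["labels"] = labels, _["prototypes"] = proto);
}

// Hungarian algorithm (Kuhn-Munkres with potentials), minimisation on an
// n x m cost matrix with n <= m. Returns the optimal total cost.
static double hungarian_min(const std::vector<std::vector<double> >& a) {
  int n = (int)a.size(), m = (int)a[0].size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (!used[j]) {
          double cur = a[i0 - 1][j - 1] - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  double cost = 0.0;
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) cost += a[p[j] - 1][j - 1];
  return cost;
}

// Maximum-weight one-to-one matching value of a nonnegative weight matrix.
// [[Rcpp::export]]
double cpp_match_max(NumericMatrix W) {
  int n = W.nrow(), m = W.ncol();
  bool flip = n > m;
  int r = flip ? m : n, c = flip ? n : m;
  double wmax = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) wmax = std::max(wmax, W(i, j));
  std::vector<std::vector<double> > cost(r, std::vector<double>(c));
  for (int i = 0; i < r; ++i)
    for (int j = 0; j < c; ++j)
      cost[i][j] = wmax - (flip ? W(j, i) : W(i, j));
  double mincost = hungarian_min(cost);
  return wmax * r - mincost;
}

// All four partition-agreement indices from two label vectors (values in
// 1..KP / 1..KQ). Pair counts come from the contingency table; MCA is the
// maximum-weight one-to-one cluster matching normalised by n; CQS is the
// adjusted Rand index mapped into [0,1] by (ARI + 1) / 2.
// [[Rcpp::export]]
NumericVector cpp_agreement(IntegerVector P, IntegerVector Q, int KP, int KQ) {
  int n = P.size();
  if (Q.size() != n) stop("label vectors differ in length");
  std::vector<double> cont(KP * KQ, 0.0);
  std::vector<double> rowm(KP, 0.0), colm(KQ, 0.0);
  for (int i = 0; i < n; ++i) {
    int a = P[i] - 1, b = Q[i] - 1;
    cont[a * KQ + b] += 1.0;
    rowm[a] += 1.0;
    colm[b] += 1.0;
  }
  double s11 = 0.0, sp = 0.0, sq = 0.0;
  for (int a = 0; a < KP; ++a)
    for (int b = 0; b < KQ; ++b) {
      double x = cont[a * KQ + b];
      s11 += x * (x - 1.0) / 2.0;
    }
  for (int a = 0; a < KP; ++a) sp += rowm[a] * (rowm[a] - 1.0) / 2.0;
  for (int b = 0; b < KQ; ++b) sq += colm[b] * (colm[b] - 1.0) / 2.0;
  double total = n * (n - 1.0) / 2.0;
  double N11 = s11, N10 = sp - s11, N01 = sq - s11;
  double N00 = total - N11 - N10 - N01;
  (void)N00;

  double jac = (N11 + N10 + N01 > 0) ? N11 / (N11 + N10 + N01) : 0.0;
  double fm = (sp > 0 && sq > 0) ? N11 / std::sqrt(sp * sq) : 0.0;

  double ari;
  double exp_idx = (total > 0) ? sp * sq / total : 0.0;
  double max_idx = 0.5 * (sp + sq);
  if (std::fabs(max_idx - exp_idx) < 1e-12) {
    ari = 1.0; // both partitions trivial in the same way
  } else {
    ari = (N11 - exp_idx) / (max_idx - exp_idx);
  }
  double cqs = (ari + 1.0) / 2.0;
  if (cqs < 0.0) cqs = 0.0;
  if (cqs > 1.0) cqs = 1.0;

  NumericMatrix W(KP, KQ);
  for (int a = 0; a < KP; ++a)
    for (int b = 0; b < KQ; ++b) W(a, b) = cont[a * KQ + b];
  double mca = cpp_match_max(W) / n;

  return NumericVector::create(_["mca"] = mca, _["jaccard"] = jac,
                               _["fm"] = fm, _["cqs"] = cqs);
}

// Pair counts alone (exported for the pair-counting primitive).
// [[Rcpp::export]]
NumericVector cpp_pair_counts(IntegerVector P, IntegerVector Q, int KP, int KQ) {
  int n = P.size();
  if (Q.size() != n) stop("label vectors differ in length");
  std::vector<double> cont(KP * KQ, 0.0);
  std::vector<double> rowm(KP, 0.0), colm(KQ, 0.0);
  for (int i = 0; i < n; ++i) {
    int a = P[i] - 1, b = Q[i] - 1;
    cont[a * KQ + b] += 1.0;
    rowm[a] += 1.0;
    colm[b] += 1.0;
  }
  double s11 = 0.0, sp = 0.0, sq = 0.0;
  for (int a = 0; a < KP; ++a)
    for (int b = 0; b < KQ; ++b) {
      double x = cont[a * KQ + b];
      s11 += x * (x - 1.0) / 2.0;
    }
  for (int a = 0; a < KP; ++a) sp += rowm[a] * (rowm[a] - 1.0) / 2.0;
  for (int b = 0; b < KQ; ++b) sq += colm[b] * (colm[b] - 1.0) / 2.0;
  double total = n * (n - 1.0) / 2.0;
  return NumericVector::create(_["n11"] = s11, _["n10"] = sp - s11,
                               _["n01"] = sq - s11,
                               _["n00"] = total - sp - sq + s11);
}
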