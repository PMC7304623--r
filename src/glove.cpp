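#include <Rcpp.h>
#include <unordered_map>
#include <random>
#include <cmath>

using namespace Rcpp;

// Accumulate symmetric, harmonically weighted co-occurrence counts over a
// corpus of index sequences. Each element of `sequences` is an integer
// vector of 1-based vocabulary indices; 0 marks an out-of-vocabulary token
// that still occupies a position (distances are counted in original token
// positions). Pairs of the same token type are skipped, so the diagonal
// stays zero. Returns the strictly-upper-triangle triplets (i < j).
// [[Rcpp::export]]
List cooc_accumulate(List sequences, int window) {
  std::unordered_map<long long, double> acc;
  int n_seq = sequences.size();
  for (int s = 0; s < n_seq; ++s) {
    IntegerVector seq = sequences[s];
    int n = seq.size();
    for (int t = 0; t < n; ++t) {
      int wi = seq[t];
      if (wi == 0) continue;
      int lim = std::min(n - 1, t + window);
      for (int u = t + 1; u <= lim; ++u) {
        int wj = seq[u];
        if (wj == 0 || wj == wi) continue;
        int a = std::min(wi, wj), b = std::max(wi, wj);
        long long key = (long long)a * 2147483647LL + b;
        acc[key] += 1.0 / (double)(u - t);
      }
    }
  }
  int m = acc.size();
  IntegerVector ii(m), jj(m);
  NumericVector xx(m);
  int k = 0;
  for (const auto& kv : acc) {
    ii[k] = (int)(kv.first / 2147483647LL);
    jj[k] = (int)(kv.first % 2147483647LL);
    xx[k] = kv.second;
    ++k;
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["x"] = xx);
}

// Weighted-least-squares embedding fit by AdaGrad SGD. For each nonzero
// co-occurrence X_ij the model minimises
//   f(X_ij) * (w_i . wt_j + b_i + bt_j - log X_ij)^2,
// f(x) = (x / x_max)^alpha capped at 1. Triplets are expected for both
// (i, j) and (j, i); entries are visited in a freshly shuffled order each
// epoch. Parameters are initialised uniformly in (-0.5/d, 0.5/d) from
// `seed`; AdaGrad accumulators start at 1.
// [[Rcpp::export]]
List glove_train_cpp(IntegerVector ti, IntegerVector tj, NumericVector tx,
                     int V, int d, int iters, double lr,
                     double x_max, double alpha, int seed) {
  const int nnz = ti.size();
  if (nnz == 0) stop("no co-occurrence mass");
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(-0.5 / d, 0.5 / d);

  NumericMatrix W(V, d), Wt(V, d);
  NumericVector b(V), bt(V);
  std::vector<double> gW((size_t)V * d, 1.0), gWt((size_t)V * d, 1.0),
      gb(V, 1.0), gbt(V, 1.0);
  for (int i = 0; i < V; ++i) {
    for (int k = 0; k < d; ++k) { W(i, k) = unif(rng); Wt(i, k) = unif(rng); }
    b[i] = unif(rng); bt[i] = unif(rng);
  }

  std::vector<int> order(nnz);
  for (int k = 0; k < nnz; ++k) order[k] = k;
  NumericVector loss_history(iters);

  for (int ep = 0; ep < iters; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double total = 0.0;
    for (int o = 0; o < nnz; ++o) {
      int k = order[o];
      int i = ti[k] - 1, j = tj[k] - 1;
      double x = tx[k];
      double dot = b[i] + bt[j] - std::log(x);
      for (int c = 0; c < d; ++c) dot += W(i, c) * Wt(j, c);
      double fx = (x < x_max) ? std::pow(x / x_max, alpha) : 1.0;
      double fdiff = fx * dot;
      total += 0.5 * fdiff * dot;
      for (int c = 0; c < d; ++c) {
        double t1 = fdiff * Wt(j, c);
        double t2 = fdiff * W(i, c);
        size_t pi = (size_t)i * d + c, pj = (size_t)j * d + c;
        W(i, c)  -= lr * t1 / std::sqrt(gW[pi]);
        Wt(j, c) -= lr * t2 / std::sqrt(gWt[pj]);
        gW[pi]  += t1 * t1;
        gWt[pj] += t2 * t2;
      }
      b[i]  -= lr * fdiff / std::sqrt(gb[i]);
      bt[j] -= lr * fdiff / std::sqrt(gbt[j]);
      gb[i]  += fdiff * fdiff;
      gbt[j] += fdiff * fdiff;
    }
    if (!std::isfinite(total)) stop("non-finite loss at epoch %d", ep + 1);
    loss_history[ep] = total;
  }
  return List::create(_["W"] = W, _["W_context"] = Wt,
                      _["b"] = b, _["b_context"] = bt,
                      _["loss_history"] = loss_history);
}
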