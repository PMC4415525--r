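#include <Rcpp.h>
using namespace Rcpp;

// Observation-model codes shared with the R side:
//   1 = logistic-distance Bernoulli   (par1 = mu, par2 = lambda, theta = {pmax, pmin})
//   2 = logistic-distance Poisson     (par1 = mu, par2 = rate,   theta = {lambda, rmin})
//   3 = per-component-pmax Bernoulli  (par1 = mu, par2 = p,      theta = {lambda, pmin})
// Probabilities are clamped to [1e-12, 1 - 1e-12] before logs so user-supplied
// extremes never produce -Inf.

static const double P_FLOOR = 1e-12;

static inline double clamp_prob(double p) {
  if (p < P_FLOOR) return P_FLOOR;
  if (p > 1.0 - P_FLOOR) return 1.0 - P_FLOOR;
  return p;
}

static inline double pair_ll(int kind, double obs, double d,
                             double p1, double p2,
                             double th1, double th2) {
  if (kind == 1) { // logistic Bernoulli: p* = 1/(1+exp((d-mu)/lambda))
    double ps = 1.0 / (1.0 + std::exp((d - p1) / p2));
    double p = clamp_prob(ps * (th1 - th2) + th2);
    return obs > 0.5 ? std::log(p) : std::log1p(-p);
  } else if (kind == 2) { // logistic Poisson: rate between rmin and r_mn
    double rs = 1.0 / (1.0 + std::exp((d - p1) / th1));
    double r = rs * (p2 - th2) + th2;
    if (r < 1e-10) r = 1e-10;
    return obs * std::log(r) - r - std::lgamma(obs + 1.0);
  } else { // per-component ceiling Bernoulli: ceiling p2, floor th2, global lambda th1
    double ps = 1.0 / (1.0 + std::exp((d - p1) / th1));
    double p = clamp_prob(ps * (p2 - th2) + th2);
    return obs > 0.5 ? std::log(p) : std::log1p(-p);
  }
}

// Log-likelihood of all observed pairs incident to entity i (1-based), for each
// candidate class 1..K. labels0 holds current labels with labels0[i-1] == 0
// (entity i excluded). Undirected relations count each unordered pair once.
// [[Rcpp::export]]
NumericVector cpp_entity_class_ll(int i, IntegerVector labels0, int K,
                                  NumericMatrix R, NumericMatrix D,
                                  LogicalMatrix mask, int kind,
                                  NumericMatrix par1, NumericMatrix par2,
                                  NumericVector theta, bool directed) {
  int N = labels0.size();
  int ii = i - 1;
  NumericVector out(K);
  double th1 = theta[0], th2 = theta[1];
  for (int j = 0; j < N; ++j) {
    int cj = labels0[j];
    if (j == ii || cj == 0) continue;
    double dij = D(ii, j);
    if (!directed) {
      if (!mask(ii, j)) continue;
      double obs = R(ii, j);
      for (int k = 0; k < K; ++k)
        out[k] += pair_ll(kind, obs, dij, par1(k, cj - 1), par2(k, cj - 1), th1, th2);
    } else {
      if (mask(ii, j)) {
        double obs = R(ii, j);
        for (int k = 0; k < K; ++k)
          out[k] += pair_ll(kind, obs, dij, par1(k, cj - 1), par2(k, cj - 1), th1, th2);
      }
      if (mask(j, ii)) {
        double obs = R(j, ii);
        for (int k = 0; k < K; ++k)
          out[k] += pair_ll(kind, obs, dij, par1(cj - 1, k), par2(cj - 1, k), th1, th2);
      }
    }
  }
  return out;
}

// Log-likelihood of the observed pairs governed by component (m, n), at scalar
// component parameters (p1, p2). Directed: ordered pairs with c_i = m, c_j = n.
// Undirected: unordered pairs, within-class handled once when m == n.
// [[Rcpp::export]]
double cpp_block_ll(int m, int n, IntegerVector labels,
                    NumericMatrix R, NumericMatrix D, LogicalMatrix mask,
                    int kind, double p1, double p2,
                    NumericVector theta, bool directed) {
  int N = labels.size();
  double th1 = theta[0], th2 = theta[1];
  double total = 0.0;
  for (int i = 0; i < N; ++i) {
    if (labels[i] != m) continue;
    for (int j = 0; j < N; ++j) {
      if (j == i || labels[j] != n) continue;
      if (!directed) {
        if (m == n && j < i) continue; // each unordered within-class pair once
        if (m != n && m > n) continue; // caller uses m <= n for undirected
        if (!mask(i, j)) continue;
        total += pair_ll(kind, R(i, j), D(i, j), p1, p2, th1, th2);
      } else {
        if (!mask(i, j)) continue;
        total += pair_ll(kind, R(i, j), D(i, j), p1, p2, th1, th2);
      }
    }
  }
  return total;
}
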